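# Candidate enumeration and donor construction. For a target codon, every
# PAM within a fixed distance on either strand yields a candidate cassette:
# the 20-bp protospacer 5' of the PAM becomes the guide, and an HDR donor is
# built carrying the codon edit plus the minimal synonymous substitutions
# needed so that neither the edited locus nor the donor is re-cut by Cas9.

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
               K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
               H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  unknown <- setdiff(chars, names(.IUPAC))
  if (length(unknown)) stop("invalid IUPAC code: ", unknown[1])
  paste0(unlist(.IUPAC[chars]), collapse = "")
}

#' Test sequences against an IUPAC pattern
#'
#' An `N` base in the sequence matches nothing (only concrete A/C/G/T bases
#' satisfy a pattern position, including `N` pattern positions).
#'
#' @param seqs Character vector, each the same length as `pattern`.
#' @param pattern IUPAC string (e.g. `"NGG"`, `"NGN"`, `"NRN"`).
#' @return Logical vector.
#' @export
matches_iupac <- function(seqs, pattern) {
  grepl(paste0("^", iupac_regex(pattern), "$"), seqs)
}

#' Enumerate PAM sites in a sequence
#'
#' Scans both strands for 3-mers matching an IUPAC PAM pattern. A
#' minus-strand site is reported at the plus-strand offset of its triplet;
#' its `pam_seq` is the reverse complement of the plus-strand triplet, read
#' 5'->3' on the minus strand.
#'
#' @param context DNA sequence to scan.
#' @param pattern IUPAC 3-mer.
#' @param window Optional 0-based half-open interval `c(start, end)`;
#'   only PAM triplets fully inside it are reported.
#' @param require_protospacer_fit Keep only sites whose 20-bp protospacer
#'   window also lies within `context`.
#' @return data.frame with columns `offset`, `strand`, `pam_seq`,
#'   `pattern`, sorted by `(offset, strand)` with `+` before `-`.
#' @export
enumerate_pams <- function(context, pattern, window = NULL,
                           require_protospacer_fit = FALSE) {
  context <- dna(context)
  if (nchar(pattern) != 3L) stop("PAM pattern must be a 3-mer")
  L <- nchar(context)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      pam_seq = character(0), pattern = character(0),
                      stringsAsFactors = FALSE)
  if (!is.null(window)) {
    if (window[1] < 0 || window[2] > L) stop("window outside context bounds")
    lo <- as.integer(window[1]); hi <- as.integer(window[2])
  } else {
    lo <- 0L; hi <- L
  }
  if (hi - lo < 3L) return(empty)
  offs <- seq.int(lo, hi - 3L)
  tri <- substring(context, offs + 1L, offs + 3L)
  plus <- matches_iupac(tri, pattern)
  minus_tri <- reverse_complement(tri)
  minus <- matches_iupac(minus_tri, pattern)
  out <- rbind(
    data.frame(offset = offs[plus], strand = rep("+", sum(plus)),
               pam_seq = tri[plus], pattern = rep(pattern, sum(plus)),
               stringsAsFactors = FALSE),
    data.frame(offset = offs[minus], strand = rep("-", sum(minus)),
               pam_seq = minus_tri[minus],
               pattern = rep(pattern, sum(minus)), stringsAsFactors = FALSE)
  )
  if (require_protospacer_fit && nrow(out)) {
    fits <- ifelse(out$strand == "+", out$offset - 20L >= 0L,
                   out$offset + 23L <= L)
    out <- out[fits, , drop = FALSE]
  }
  out <- out[order(out$offset, out$strand == "-"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Guide (protospacer) for a PAM site
#'
#' The protospacer is the 20-mer immediately 5' of the PAM on the PAM's
#' strand. `seed4`/`seed12` are its PAM-proximal 4- and 12-mers;
#' `proto_start` and `seed12_start` are 0-based plus-strand starts of the
#' corresponding context windows.
#'
#' @param context DNA sequence.
#' @param offset 0-based plus-strand offset of the PAM triplet.
#' @param strand `"+"` or `"-"`.
#' @return List with `protospacer`, `seed4`, `seed12`, `gc`,
#'   `proto_start`, `seed12_start`, or `NULL` when the protospacer window
#'   falls outside `context`.
#' @export
guide_for_pam <- function(context, offset, strand) {
  L <- nchar(context)
  if (strand == "+") {
    if (offset - 20L < 0L) return(NULL)
    proto <- substr(context, offset - 20L + 1L, offset)
    proto_start <- offset - 20L
    seed12_start <- offset - 12L
  } else {
    if (offset + 23L > L) return(NULL)
    proto <- reverse_complement(substr(context, offset + 4L, offset + 23L))
    proto_start <- offset + 3L
    seed12_start <- offset + 3L
  }
  list(protospacer = proto,
       seed4 = substr(proto, 17L, 20L),
       seed12 = substr(proto, 9L, 20L),
       gc = gc_fraction(proto),
       proto_start = as.integer(proto_start),
       seed12_start = as.integer(seed12_start))
}

#' PAM-codon distance
#'
#' Number of bases strictly between the codon interval and the PAM triplet
#' on the plus strand; 0 when they overlap or abut.
#'
#' @param pam_offset 0-based start of the PAM triplet.
#' @param codon_offset 0-based start of the codon.
#' @return Non-negative integer distance.
#' @export
pam_codon_distance <- function(pam_offset, codon_offset) {
  d <- pmax(codon_offset - (pam_offset + 3L), pam_offset - (codon_offset + 3L))
  pmax(d, 0L)
}

#' Candidate PAMs for a target codon
#'
#' PAM sites on either strand whose gap to the codon is at most
#' `max_distance` bases and whose 20-bp protospacer fits inside the
#' context.
#'
#' @param target A [gene_target()].
#' @param site A [codon_site()] of `target`.
#' @param pattern IUPAC PAM pattern.
#' @param max_distance Maximum PAM-codon gap (default 20 bp).
#' @return data.frame of PAM sites with an extra `distance` column.
#' @export
candidate_pams_for_codon <- function(target, site, pattern,
                                     max_distance = 20L) {
  L <- nchar(target$context)
  lo <- max(0L, site$offset - (max_distance + 3L))
  hi <- min(L, site$offset + 3L + max_distance + 3L)
  pams <- enumerate_pams(target$context, pattern, window = c(lo, hi),
                         require_protospacer_fit = TRUE)
  if (!nrow(pams)) { pams$distance <- integer(0); return(pams) }
  pams$distance <- pam_codon_distance(pams$offset, site$offset)
  pams <- pams[pams$distance <= max_distance, , drop = FALSE]
  rownames(pams) <- NULL
  pams
}

# ---- Substitutions ---------------------------------------------------------

empty_substitutions <- function() {
  data.frame(offset = integer(0), ref = character(0), alt = character(0),
             purpose = character(0), stringsAsFactors = FALSE)
}

#' Apply point substitutions to a sequence
#'
#' @param context DNA sequence.
#' @param subs data.frame with 0-based `offset`, `ref`, `alt` columns;
#'   each `ref` must equal the current base at its offset.
#' @return The edited sequence.
#' @export
apply_substitutions <- function(context, subs) {
  if (is.null(subs) || nrow(subs) == 0L) return(context)
  if (any(subs$offset < 0L | subs$offset >= nchar(context))) {
    stop("substitution offset outside context")
  }
  cur <- substring(context, subs$offset + 1L, subs$offset + 1L)
  if (any(cur != subs$ref)) {
    bad <- which(cur != subs$ref)[1]
    stop("ref mismatch at offset ", subs$offset[bad], ": expected ",
         subs$ref[bad], ", context has ", cur[bad])
  }
  out <- context
  for (i in seq_len(nrow(subs))) {
    substr(out, subs$offset[i] + 1L, subs$offset[i] + 1L) <- subs$alt[i]
  }
  out
}

#' Plan the substitutions implementing one codon edit
#'
#' @param site A [codon_site()].
#' @param new_codon Replacement 3-mer; must differ from the wild-type codon.
#' @return data.frame of 1-3 substitutions with purpose `codon_edit`.
#' @export
plan_codon_edit <- function(site, new_codon) {
  new_codon <- dna(new_codon)
  if (nchar(new_codon) != 3L) stop("new_codon must be a 3-mer")
  if (new_codon == site$wt_codon) {
    stop("new codon equals wild-type codon ", site$wt_codon, " (no-op edit)")
  }
  wt <- strsplit(site$wt_codon, "", fixed = TRUE)[[1]]
  nw <- strsplit(new_codon, "", fixed = TRUE)[[1]]
  diff <- which(wt != nw)
  data.frame(offset = site$offset + diff - 1L, ref = wt[diff],
             alt = nw[diff], purpose = "codon_edit", stringsAsFactors = FALSE)
}

# ---- Re-cutting policy -----------------------------------------------------

# A locus is still cleavable iff the 20-mer at the guide's position exactly
# equals the (wild-type) protospacer AND the adjacent triplet still matches
# the design PAM pattern, both read on the guide's strand.
is_cleavable <- function(edited_context, pam, guide, pattern = pam$pattern) {
  if (pam$strand == "+") {
    cur_proto <- substr(edited_context, pam$offset - 20L + 1L, pam$offset)
    cur_pam <- substr(edited_context, pam$offset + 1L, pam$offset + 3L)
  } else {
    cur_proto <- reverse_complement(
      substr(edited_context, pam$offset + 4L, pam$offset + 23L))
    cur_pam <- reverse_complement(
      substr(edited_context, pam$offset + 1L, pam$offset + 3L))
  }
  identical(cur_proto, guide$protospacer) && matches_iupac(cur_pam, pattern)
}

# Codon indices of `target` whose interval intersects [start, end).
codons_overlapping <- function(target, start, end) {
  os <- target$orf_start
  first <- max(1L, (max(start, os) - os) %/% 3L + 1L)
  last <- min(n_codons(target), (min(end, os + target$orf_length) - 1L - os)
              %/% 3L + 1L)
  if (first > last) integer(0) else seq.int(first, last)
}

# All synonymous single-codon replacements of codon j as substitution sets
# (offsets are context coordinates; ref taken from the current context).
synonymous_replacements <- function(context, target, j, ct) {
  off <- target$orf_start + 3L * (j - 1L)
  cur <- substr(context, off + 1L, off + 3L)
  alts <- tryCatch(synonymous_codons(ct, cur), error = function(e) character(0))
  lapply(alts, function(alt) {
    a <- strsplit(alt, "", fixed = TRUE)[[1]]
    c0 <- strsplit(cur, "", fixed = TRUE)[[1]]
    d <- which(a != c0)
    data.frame(offset = off + d - 1L, ref = c0[d], alt = a[d],
               purpose = "pam_kill", stringsAsFactors = FALSE)
  })
}

# Deterministic candidate ordering: fewest substitutions, then closest to
# the PAM, then lexicographically smallest alt base of the closest
# substitution, then a canonical string.
order_candidates <- function(cands, pam_offset) {
  if (!length(cands)) return(cands)
  keys <- vapply(cands, function(s) {
    dist <- min(pmax(pmax(pam_offset - s$offset, s$offset - (pam_offset + 2L)),
                     0L))
    closest <- s[which.min(pmax(pmax(pam_offset - s$offset,
                                     s$offset - (pam_offset + 2L)), 0L)), ]
    sprintf("%02d|%03d|%s|%s", nrow(s), dist, closest$alt[1],
            paste(s$offset, s$alt, sep = ":", collapse = ","))
  }, character(1))
  cands[order(keys)]
}

count_matches <- function(x, pattern) {
  if (nchar(x) < nchar(pattern)) return(0L)
  sum(gregexpr(pattern, x, fixed = TRUE)[[1]] > 0L)
}

# polyT / donor-self-targeting guard: a candidate may not create a new
# TTTTT run or a new perfect protospacer match within the donor region.
candidate_guard_ok <- function(context, target, pam, guide, existing_subs,
                               cand) {
  all_subs <- rbind(existing_subs, cand)
  span_lo <- max(0L, min(all_subs$offset) - 50L)
  span_hi <- min(nchar(context), max(all_subs$offset) + 51L)
  win <- function(subs) {
    s <- apply_substitutions(context, subs)
    w <- substr(s, span_lo + 1L, span_hi)
    if (pam$strand == "-") w <- reverse_complement(w)
    w
  }
  before <- paste0(win(existing_subs), guide$protospacer)
  after <- paste0(win(all_subs), guide$protospacer)
  if (count_matches(after, "TTTTT") > count_matches(before, "TTTTT")) {
    return(FALSE)
  }
  donor_hits <- function(w) count_matches(w, guide$protospacer) +
    count_matches(reverse_complement(w), guide$protospacer)
  donor_hits(win(all_subs)) <= donor_hits(win(existing_subs))
}

#' Synonymous substitutions preventing re-cutting
#'
#' Given a codon edit already planned at a locus, finds the minimal set of
#' additional synonymous substitutions such that the edited locus no longer
#' satisfies the cleavability predicate (exact 20-mer protospacer match
#' plus a pattern-matching PAM). Preference order: (1) synonymously destroy
#' a pattern-essential PAM base; (2) place one synonymous mismatch in the
#' PAM-proximal 4-bp seed; (3) place two synonymous mismatches in the
#' PAM-proximal 10 bases. Candidates that would create a new polyT run or a
#' new protospacer match inside the donor are rejected.
#'
#' @param target A [gene_target()].
#' @param pam One PAM site (list/row with `offset`, `strand`, `pattern`).
#' @param guide The matching [guide_for_pam()] result.
#' @param existing_subs Substitutions already planned (the codon edit).
#' @param ct A [codon_table()].
#' @param memo Optional environment caching per-codon synonymous
#'   replacement sets across calls on the same target (internal speed-up;
#'   safe because replacements are computed on wild-type context and the
#'   edited codon is excluded).
#' @return data.frame of additional substitutions (possibly empty when the
#'   codon edit itself destroys cleavability), or `NULL` when no synonymous
#'   option exists (the design is infeasible).
#' @export
eliminate_recutting <- function(target, pam, guide, existing_subs,
                                ct = codon_table(), memo = NULL) {
  context <- target$context
  edited <- apply_substitutions(context, existing_subs)
  if (!is_cleavable(edited, pam, guide)) return(empty_substitutions())

  p <- pam$offset
  locked <- unique(codons_overlapping(
    target, min(existing_subs$offset), max(existing_subs$offset) + 1L))
  pam_iv <- c(p, p + 3L)
  if (pam$strand == "+") {
    seed4_iv <- c(p - 4L, p); prox10_iv <- c(p - 10L, p)
  } else {
    seed4_iv <- c(p + 3L, p + 7L); prox10_iv <- c(p + 3L, p + 13L)
  }

  repl_for_codon <- function(j) {
    if (is.null(memo)) return(synonymous_replacements(context, target, j, ct))
    key <- as.character(j)
    if (is.null(memo[[key]])) {
      memo[[key]] <- synonymous_replacements(context, target, j, ct)
    }
    memo[[key]]
  }
  cands_in <- function(iv) {
    js <- setdiff(codons_overlapping(target, iv[1], iv[2]), locked)
    unlist(lapply(js, repl_for_codon), recursive = FALSE)
  }
  in_iv <- function(s, iv) s$offset >= iv[1] & s$offset < iv[2]

  finish <- function(cand, purpose_default) {
    cand$purpose <- ifelse(in_iv(cand, pam_iv), "pam_kill", purpose_default)
    rownames(cand) <- NULL
    cand
  }

  # (1) kill the PAM pattern
  for (cand in order_candidates(cands_in(pam_iv), p)) {
    ed2 <- apply_substitutions(edited, cand)
    cur_pam <- substr(ed2, p + 1L, p + 3L)
    if (pam$strand == "-") cur_pam <- reverse_complement(cur_pam)
    if (matches_iupac(cur_pam, pam$pattern)) next
    if (is_cleavable(ed2, pam, guide)) next
    if (!candidate_guard_ok(context, target, pam, guide, existing_subs, cand))
      next
    return(finish(cand, "pam_kill"))
  }
  # (2) one mismatch in the 4-bp seed
  for (cand in order_candidates(cands_in(seed4_iv), p)) {
    if (!any(in_iv(cand, seed4_iv))) next
    ed2 <- apply_substitutions(edited, cand)
    if (is_cleavable(ed2, pam, guide)) next
    if (!candidate_guard_ok(context, target, pam, guide, existing_subs, cand))
      next
    return(finish(cand, "protospacer_kill"))
  }
  # (3) two mismatches in the PAM-proximal 10 bases
  singles <- cands_in(prox10_iv)
  pool <- singles[vapply(singles, function(s) sum(in_iv(s, prox10_iv)) >= 1L,
                         logical(1))]
  pairs <- list()
  if (length(pool) >= 2L) {
    codon_of <- vapply(pool, function(s)
      (min(s$offset) - target$orf_start) %/% 3L, numeric(1))
    for (i in seq_along(pool)) for (j in seq_along(pool)) {
      if (i < j && codon_of[i] != codon_of[j]) {
        pairs[[length(pairs) + 1L]] <- rbind(pool[[i]], pool[[j]])
      }
    }
  }
  combos <- c(singles, pairs)
  combos <- combos[vapply(combos, function(s) sum(in_iv(s, prox10_iv)) >= 2L,
                          logical(1))]
  for (cand in order_candidates(combos, p)) {
    ed2 <- apply_substitutions(edited, cand)
    if (is_cleavable(ed2, pam, guide)) next
    if (!candidate_guard_ok(context, target, pam, guide, existing_subs, cand))
      next
    return(finish(cand, "protospacer_kill"))
  }
  NULL
}

# ---- Donors and cassettes --------------------------------------------------

#' Build an HDR donor around a set of substitutions
#'
#' The donor spans the outermost substituted bases plus exactly 50 bp of
#' unmodified homology arm on each side. When the guide lies on the minus
#' strand the emitted sequence is reverse-complemented (minimizes hairpin
#' formation with the downstream guide in the synthesized cassette).
#'
#' @param target A [gene_target()].
#' @param substitutions data.frame of substitutions (non-empty), or `NULL`
#'   when `deletion` is given.
#' @param strand Strand of the guide paired with this donor.
#' @param deletion Optional 0-based half-open interval `c(start, end)` to
#'   delete; arms then flank the deleted interval and the core is empty.
#' @return List of class `donor` with `start`, `end`, `left_arm`,
#'   `right_arm`, `core`, `emitted_seq`, `strand`, `substitutions`,
#'   `deletion`.
#' @export
build_donor <- function(target, substitutions, strand = "+",
                        deletion = NULL) {
  context <- target$context
  L <- nchar(context)
  if (is.null(deletion)) {
    if (is.null(substitutions) || nrow(substitutions) == 0L) {
      stop("donor requires at least one substitution")
    }
    lo <- min(substitutions$offset); hi <- max(substitutions$offset)
    start <- lo - 50L; end <- hi + 51L
    if (start < 0L || end > L) {
      stop("insufficient flank for 50-bp homology arms (need [",
           start, ", ", end, ") in 0..", L, ")")
    }
    edited <- apply_substitutions(context, substitutions)
    window <- substr(edited, start + 1L, end)
    core <- substr(window, 51L, nchar(window) - 50L)
  } else {
    start <- deletion[1] - 50L; end <- deletion[2] + 50L
    if (start < 0L || end > L) stop("insufficient flank for deletion donor")
    if (!is.null(substitutions) && nrow(substitutions) > 0L) {
      stop("deletion donors do not carry extra substitutions")
    }
    substitutions <- empty_substitutions()
    window <- paste0(substr(context, start + 1L, deletion[1]),
                     substr(context, deletion[2] + 1L, end))
    core <- ""
  }
  emitted <- if (strand == "-") reverse_complement(window) else window
  structure(list(start = as.integer(start), end = as.integer(end),
                 left_arm = substr(context, start + 1L, start + 50L),
                 right_arm = substr(context, end - 50L + 1L, end),
                 core = core, emitted_seq = emitted, strand = strand,
                 substitutions = substitutions, deletion = deletion),
            class = "donor")
}

#' Assemble the synthesized cassette oligo
#'
#' The oligo is `adapter5 + donor + guide + adapter3`: the 20-bp guide is
#' appended to the 3' end of the donor, establishing donor-guide linkage,
#' and assembly adapters are added outside.
#'
#' @param donor A [build_donor()] result.
#' @param protospacer The 20-mer guide sequence.
#' @param adapters Character pair `c(adapter5, adapter3)`.
#' @return List with `oligo` (full synthesized sequence) and `core`
#'   (donor+guide, the transcribed part scanned by the polyT filter).
#' @export
assemble_cassette <- function(donor, protospacer, adapters = c("", "")) {
  if (nchar(protospacer) != 20L) stop("protospacer must be a 20-mer")
  core <- paste0(donor$emitted_seq, protospacer)
  list(oligo = paste0(adapters[1], core, adapters[2]), core = core)
}
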
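# Whole-library orchestration: saturation mode (every codon x 21 target
# classes), stop-scan mode (every codon -> stop), custom edits, the
# design-landscape matrix, and oligo-pool export.

#' Design specification
#'
#' @param pam_pattern IUPAC PAM (e.g. `"NGN"`, `"NGG"`, `"NRN"`).
#' @param window Maximum PAM-codon distance in bp.
#' @param k Cassettes kept per codon swap.
#' @param mode One of `saturation`, `stop_scan`, `custom`.
#' @param codon_range 1-based inclusive codon interval `c(first, last)`;
#'   default all codons except the start codon and a terminal stop codon.
#' @param adapters Character pair of 5'/3' assembly adapters.
#' @param ct A [codon_table()].
#' @param strict_gc Make the 30-80% guide GC range a hard filter.
#' @param genome Optional named character vector (or FASTA path) indexed
#'   for 12-bp-seed off-target counting; `NULL` treats all off-target
#'   counts as 0.
#' @param context_location Optional list `(seq_id, offset)` placing the
#'   target context inside `genome`, so each guide's on-target seed hit is
#'   subtracted (and its absence raises a consistency error). `NULL`
#'   assumes the context is not part of `genome`.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(pam_pattern = "NGN", window = 20L, k = 4L,
                        mode = c("saturation", "stop_scan", "custom"),
                        codon_range = NULL, adapters = c("", ""),
                        ct = codon_table(), strict_gc = FALSE,
                        genome = NULL, context_location = NULL) {
  mode <- match.arg(mode)
  stopifnot(window >= 0L, k >= 1L)
  structure(list(pam_pattern = pam_pattern, window = as.integer(window),
                 k = as.integer(k), mode = mode, codon_range = codon_range,
                 adapters = adapters, ct = ct, strict_gc = strict_gc,
                 genome = genome, context_location = context_location),
            class = "design_spec")
}

# Default codon range: exclude the start codon and the terminal stop codon.
resolve_codon_range <- function(target, spec) {
  if (!is.null(spec$codon_range)) {
    r <- seq.int(spec$codon_range[1], spec$codon_range[2])
    if (min(r) < 1L || max(r) > n_codons(target)) {
      stop("codon_range outside ORF")
    }
    return(setdiff(r, 1L))
  }
  nc <- n_codons(target)
  r <- seq_len(nc)[-1L]
  if (nc > 1L && codon_site(target, nc)$wt_aa == "*") r <- r[-length(r)]
  r
}

cassette_id <- function(gene, codon_index, wt_aa, new_aa, rank) {
  sprintf("%s|c%d|%s%d%s|r%d", gene, codon_index, wt_aa, codon_index,
          new_aa, rank)
}

# Build every candidate cassette (pre polyT / pre top-k) for one
# (codon site, new codon) pair. Returns list(cassettes, failures) where
# failures is a character vector of per-candidate reasons.
candidates_for_edit <- function(target, site, new_codon, spec, pams,
                                seed_index = NULL, memo = NULL) {
  fails <- character(0)
  out <- list()
  if (nrow(pams) == 0L) return(list(cassettes = out, failures = fails))
  codon_edit <- plan_codon_edit(site, new_codon)
  new_aa <- translate_dna(new_codon)
  category <- if (new_aa == "*") "stop"
    else if (new_aa == site$wt_aa) "synonymous" else "missense"
  for (r in seq_len(nrow(pams))) {
    pam <- as.list(pams[r, ])
    guide <- guide_for_pam(target$context, pam$offset, pam$strand)
    if (is.null(guide)) { fails <- c(fails, "flank_bounds"); next }
    kill <- eliminate_recutting(target, pam, guide, codon_edit, spec$ct,
                                memo = memo)
    if (is.null(kill)) { fails <- c(fails, "synonymous_kill_infeasible"); next }
    subs <- rbind(codon_edit, kill)
    subs <- subs[order(subs$offset), , drop = FALSE]
    rownames(subs) <- NULL
    donor <- tryCatch(build_donor(target, subs, strand = pam$strand),
                      error = function(e) NULL)
    if (is.null(donor)) { fails <- c(fails, "flank_bounds"); next }
    asm <- assemble_cassette(donor, guide$protospacer, spec$adapters)
    offt <- 0L
    if (!is.null(seed_index)) {
      on_target <- NULL
      if (!is.null(spec$context_location)) {
        on_target <- list(seq_id = spec$context_location$seq_id,
                          offset = spec$context_location$offset +
                            guide$seed12_start,
                          strand = pam$strand)
      }
      offt <- count_offtargets(seed_index, guide, on_target)
    }
    out[[length(out) + 1L]] <- list(
      id = NA_character_, gene = target$gene_id,
      codon_index = site$codon_index, wt_codon = site$wt_codon,
      wt_aa = site$wt_aa, new_codon = new_codon, new_aa = new_aa,
      category = category, pam = pam, guide = guide, donor = donor,
      oligo = asm$oligo, core = asm$core, substitutions = subs,
      distance = pam$distance, seed4_purine = seed_purine_fraction(guide$seed4),
      gc = guide$gc, gc_in_range = gc_in_range(guide$gc),
      offtargets = offt, rank = NA_integer_)
  }
  list(cassettes = out, failures = fails)
}

# Shared engine behind saturation / stop-scan modes.
design_library <- function(target, spec, classes) {
  range <- resolve_codon_range(target, spec)
  seed_index <- NULL
  if (!is.null(spec$genome)) {
    seed_index <- if (inherits(spec$genome, "seed_index")) spec$genome
      else build_seed_index(spec$genome, k = 12L,
                            pam_pattern = spec$pam_pattern)
  }
  cassettes <- list()
  missing <- list()
  memo <- new.env(parent = emptyenv())  # synonymous-replacement cache
  seen_variants <- character(0)  # library-wide unique-variant constraint
  avail <- matrix(0L, nrow = length(range), ncol = length(classes),
                  dimnames = list(as.character(range), classes))
  for (ci in seq_along(range)) {
    idx <- range[ci]
    site <- codon_site(target, idx)
    pams <- candidate_pams_for_codon(target, site, spec$pam_pattern,
                                     spec$window)
    for (cl in classes) {
      new_codon <- design_codon_for_class(spec$ct, site$wt_codon, cl)
      slot_missing <- function(n, reason) {
        if (n > 0L) missing[[length(missing) + 1L]] <<- data.frame(
          codon_index = idx, class = cl,
          new_codon = if (is.na(new_codon)) "" else new_codon,
          n_missing = n, reason = reason, stringsAsFactors = FALSE)
      }
      if (is.na(new_codon)) { slot_missing(spec$k, "no_codon_change"); next }
      cand <- candidates_for_edit(target, site, new_codon, spec, pams,
                                  seed_index, memo = memo)
      n_polyT <- sum(vapply(cand$cassettes, function(x) has_polyT(x$core),
                            logical(1)))
      avail[ci, cl] <- length(cand$cassettes) - n_polyT
      sel <- rank_and_select(cand$cassettes, spec$k, spec$strict_gc,
                             exclude_variants = seen_variants)
      for (i in seq_along(sel)) {
        sel[[i]]$id <- cassette_id(target$gene_id, idx, site$wt_aa,
                                   sel[[i]]$new_aa, sel[[i]]$rank)
        seen_variants <- c(seen_variants,
                           cassette_variant_key(sel[[i]]))
        cassettes[[length(cassettes) + 1L]] <- sel[[i]]
      }
      short <- spec$k - length(sel)
      if (short > 0L) {
        reason <- if (nrow(pams) == 0L) {
          "no_pam_in_window"
        } else if (length(cand$cassettes) == 0L) {
          if (any(cand$failures == "synonymous_kill_infeasible"))
            "synonymous_kill_infeasible" else "flank_bounds"
        } else if (length(sel) == 0L && n_polyT == length(cand$cassettes)) {
          "polyT_all"
        } else {
          "no_pam_in_window"
        }
        slot_missing(short, reason)
      }
    }
  }
  missing <- if (length(missing)) do.call(rbind, missing) else
    data.frame(codon_index = integer(0), class = character(0),
               new_codon = character(0), n_missing = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  report <- library_report(target, spec, classes, range, cassettes, missing,
                           avail)
  structure(list(cassettes = cassettes, report = report, spec = spec,
                 target = target), class = "designed_library")
}

library_report <- function(target, spec, classes, range, cassettes, missing,
                           avail) {
  n_slots <- length(range) * length(classes) * spec$k
  n_missing <- sum(missing$n_missing)
  per_codon_avail <- rowSums(avail)
  list(
    gene = target$gene_id, pam_pattern = spec$pam_pattern, k = spec$k,
    mode = spec$mode, classes = classes, codons = range,
    sort_keys = c("offtargets", "distance", "seed4_purine", "gc_in_range"),
    total_cassettes = length(cassettes),
    total_slots = n_slots, missing_slots = n_missing,
    design_success_rate = if (n_slots > 0) 1 - n_missing / n_slots else NA,
    missing = missing,
    available_matrix = avail,
    pct_codons_uneditable = 100 * mean(per_codon_avail == 0),
    pct_codons_single_cassette = 100 * mean(per_codon_avail == 1),
    pct_codons_multi_cassette = 100 * mean(per_codon_avail >= 2),
    # alternative (per-target) reading of the single-cassette statistic
    pct_slots_single_candidate = 100 * mean(avail == 1)
  )
}

#' Design a saturation editing library
#'
#' For every codon in range and each of 21 target classes (the
#' representative codon of each of the 20 amino acids -- the wild-type
#' amino acid giving the synonymous design -- plus a stop codon), designs
#' and ranks candidate cassettes and keeps up to `k` per codon swap.
#'
#' @param target A [gene_target()].
#' @param spec A [design_spec()] with `mode = "saturation"`.
#' @return A `designed_library`: list of cassettes plus a report with
#'   per-slot missing reasons and landscape statistics.
#' @export
design_saturation_library <- function(target, spec = design_spec()) {
  spec$mode <- "saturation"
  design_library(target, spec, saturation_classes())
}

#' Design a stop-scan library
#'
#' One target class per codon: replacement by the configured stop codon.
#'
#' @inheritParams design_saturation_library
#' @return A `designed_library`.
#' @export
design_stop_library <- function(target, spec = design_spec(mode = "stop_scan")) {
  spec$mode <- "stop_scan"
  design_library(target, spec, "*")
}

#' Design individual custom-edit cassettes
#'
#' Each edit is either `list(type = "codon", codon_index, new_codon)`
#' (identical to one saturation slot) or `list(type = "deletion", start,
#' end)` with a 0-based half-open context interval to delete. Deletion
#' donors carry 50-bp arms flanking the deleted interval and require the
#' deletion itself to disrupt the protospacer/PAM (no synonymity is
#' defined across a frameshift).
#'
#' @param target A [gene_target()].
#' @param edits List of edit descriptions.
#' @param spec A [design_spec()].
#' @return A `designed_library` whose report lists infeasible edits.
#' @export
design_custom <- function(target, edits, spec = design_spec(mode = "custom")) {
  spec$mode <- "custom"
  cassettes <- list()
  missing <- list()
  for (e in edits) {
    if (e$type == "codon") {
      site <- codon_site(target, e$codon_index)
      pams <- candidate_pams_for_codon(target, site, spec$pam_pattern,
                                       spec$window)
      cand <- candidates_for_edit(target, site, e$new_codon, spec, pams)
      sel <- rank_and_select(cand$cassettes, spec$k, spec$strict_gc)
      for (i in seq_along(sel)) {
        sel[[i]]$id <- cassette_id(target$gene_id, e$codon_index, site$wt_aa,
                                   sel[[i]]$new_aa, sel[[i]]$rank)
        cassettes[[length(cassettes) + 1L]] <- sel[[i]]
      }
      if (length(sel) < spec$k) {
        missing[[length(missing) + 1L]] <- data.frame(
          codon_index = e$codon_index, class = "custom",
          new_codon = e$new_codon, n_missing = spec$k - length(sel),
          reason = if (nrow(pams) == 0L) "no_pam_in_window" else "custom",
          stringsAsFactors = FALSE)
      }
    } else if (e$type == "deletion") {
      sel <- design_deletion(target, e, spec)
      if (length(sel)) {
        cassettes <- c(cassettes, sel)
      } else {
        missing[[length(missing) + 1L]] <- data.frame(
          codon_index = NA_integer_, class = "deletion",
          new_codon = sprintf("del%d-%d", e$start, e$end),
          n_missing = spec$k, reason = "no_pam_in_window",
          stringsAsFactors = FALSE)
      }
    } else stop("unknown edit type: ", e$type)
  }
  missing <- if (length(missing)) do.call(rbind, missing) else NULL
  structure(list(cassettes = cassettes,
                 report = list(gene = target$gene_id, mode = "custom",
                               total_cassettes = length(cassettes),
                               missing = missing),
                 spec = spec, target = target),
            class = "designed_library")
}

# Deletion edits: only PAMs whose protospacer-PAM 23-mer overlaps the
# deleted interval are usable (the deletion then prevents re-cutting).
design_deletion <- function(target, e, spec) {
  del <- c(e$start, e$end)
  pams <- enumerate_pams(target$context, spec$pam_pattern,
                         require_protospacer_fit = TRUE)
  if (!nrow(pams)) return(list())
  out <- list()
  for (r in seq_len(nrow(pams))) {
    pam <- as.list(pams[r, ])
    guide <- guide_for_pam(target$context, pam$offset, pam$strand)
    site_lo <- min(guide$proto_start, pam$offset)
    site_hi <- max(guide$proto_start + 20L, pam$offset + 3L)
    if (site_hi <= del[1] || site_lo >= del[2]) next  # deletion misses site
    donor <- tryCatch(build_donor(target, NULL, strand = pam$strand,
                                  deletion = del),
                      error = function(e) NULL)
    if (is.null(donor)) next
    asm <- assemble_cassette(donor, guide$protospacer, spec$adapters)
    d <- pmax(pmax(del[1] - (pam$offset + 3L), pam$offset - del[2]), 0L)
    out[[length(out) + 1L]] <- list(
      id = NA_character_, gene = target$gene_id, codon_index = NA_integer_,
      wt_codon = "", wt_aa = "", new_codon = "",
      new_aa = "", category = "deletion", pam = pam, guide = guide,
      donor = donor, oligo = asm$oligo, core = asm$core,
      substitutions = empty_substitutions(), distance = d,
      seed4_purine = seed_purine_fraction(guide$seed4), gc = guide$gc,
      gc_in_range = gc_in_range(guide$gc), offtargets = 0L,
      rank = NA_integer_)
  }
  sel <- rank_and_select(out, spec$k, spec$strict_gc)
  for (i in seq_along(sel)) {
    sel[[i]]$id <- sprintf("%s|del%d-%d|r%d", target$gene_id, del[1], del[2],
                           sel[[i]]$rank)
  }
  sel
}

#' Design-landscape matrix
#'
#' Counts, per codon and target class, the candidate cassettes surviving
#' the polyT filter before top-k truncation (the design-space view used to
#' compare PAM patterns), together with summary percentages: codons with
#' zero candidates across all 21 targets ("not editable") and codons whose
#' total candidate count is exactly one.
#'
#' @param target A [gene_target()].
#' @param spec A [design_spec()].
#' @return List with `matrix` (codons x classes), `pct_codons_uneditable`,
#'   `pct_codons_single_cassette`, `pct_slots_single_candidate`.
#' @export
landscape_matrix <- function(target, spec = design_spec()) {
  classes <- if (spec$mode == "stop_scan") "*" else saturation_classes()
  lib <- design_library(target, spec, classes)
  rep <- lib$report
  list(matrix = rep$available_matrix,
       pct_codons_uneditable = rep$pct_codons_uneditable,
       pct_codons_single_cassette = rep$pct_codons_single_cassette,
       pct_slots_single_candidate = rep$pct_slots_single_candidate)
}

#' @export
print.designed_library <- function(x, ...) {
  r <- x$report
  cat("<designed_library> ", r$gene, " (", r$mode, ", PAM ",
      x$spec$pam_pattern, "): ", r$total_cassettes, " cassettes", sep = "")
  if (!is.null(r$missing_slots)) cat(", ", r$missing_slots, " missing slots",
                                     sep = "")
  cat("\n")
  invisible(x)
}

# ---- Export / import -------------------------------------------------------

format_substitutions <- function(subs) {
  if (nrow(subs) == 0L) return("")
  paste(sprintf("%d:%s>%s", subs$offset, subs$ref, subs$alt), collapse = ";")
}

parse_substitutions <- function(x) {
  if (is.na(x) || x == "") return(empty_substitutions())
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "[:>]")
  data.frame(offset = as.integer(vapply(parts, `[`, character(1), 1L)),
             ref = vapply(parts, `[`, character(1), 2L),
             alt = vapply(parts, `[`, character(1), 3L),
             purpose = NA_character_, stringsAsFactors = FALSE)
}

#' Cassette manifest as a data.frame
#'
#' @param lib A `designed_library` (or plain list of cassettes).
#' @return data.frame, one row per cassette.
#' @export
library_manifest <- function(lib) {
  cassettes <- if (inherits(lib, "designed_library")) lib$cassettes else lib
  if (!length(cassettes)) stop("empty library")
  data.frame(
    id = vapply(cassettes, function(x) x$id, character(1)),
    codon_index = vapply(cassettes, function(x)
      as.integer(x$codon_index), integer(1)),
    wt_codon = vapply(cassettes, function(x) x$wt_codon, character(1)),
    new_codon = vapply(cassettes, function(x) x$new_codon, character(1)),
    category = vapply(cassettes, function(x) x$category, character(1)),
    guide = vapply(cassettes, function(x) x$guide$protospacer, character(1)),
    pam = vapply(cassettes, function(x) x$pam$pam_seq, character(1)),
    pam_offset = vapply(cassettes, function(x)
      as.integer(x$pam$offset), integer(1)),
    strand = vapply(cassettes, function(x) x$pam$strand, character(1)),
    donor = vapply(cassettes, function(x) x$donor$emitted_seq, character(1)),
    oligo = vapply(cassettes, function(x) x$oligo, character(1)),
    substitutions = vapply(cassettes, function(x)
      format_substitutions(x$substitutions), character(1)),
    rank = vapply(cassettes, function(x) as.integer(x$rank), integer(1)),
    distance = vapply(cassettes, function(x)
      as.integer(x$distance), integer(1)),
    seed4_purine = vapply(cassettes, function(x) x$seed4_purine, numeric(1)),
    gc = vapply(cassettes, function(x) x$gc, numeric(1)),
    offtargets = vapply(cassettes, function(x)
      as.integer(x$offtargets), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Export a designed library
#'
#' Writes the oligo pool as FASTA (record id = cassette id), a TSV
#' manifest, and the design report as JSON.
#'
#' @param lib A `designed_library`.
#' @param prefix Output path prefix; files `<prefix>.oligos.fasta`,
#'   `<prefix>.manifest.tsv`, `<prefix>.report.json` are created.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_library <- function(lib, prefix) {
  man <- library_manifest(lib)
  paths <- c(fasta = paste0(prefix, ".oligos.fasta"),
             manifest = paste0(prefix, ".manifest.tsv"),
             report = paste0(prefix, ".report.json"))
  oligos <- man$oligo
  names(oligos) <- man$id
  write_fasta(oligos, paths[["fasta"]])
  utils::write.table(man, paths[["manifest"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rep <- lib$report
  rep$available_matrix <- NULL  # large; landscape TSV covers it
  jsonlite::write_json(rep, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Read a cassette manifest back from TSV
#'
#' Round-trips [export_library()] output; the quantifier takes this as its
#' designed-library reference.
#'
#' @param path Manifest TSV path.
#' @return data.frame as produced by [library_manifest()].
#' @export
read_library_manifest <- function(path) {
  man <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  for (col in c("codon_index", "pam_offset", "rank", "distance",
                "offtargets")) {
    man[[col]] <- as.integer(man[[col]])
  }
  for (col in c("seed4_purine", "gc")) man[[col]] <- as.numeric(man[[col]])
  if (anyDuplicated(man$id)) stop("duplicate cassette ids in manifest")
  man
}
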
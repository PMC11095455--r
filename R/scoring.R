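# Cassette filters and rank features. Candidates with a polyT run are
# discarded (a run of >= 5 T's terminates transcription from the type III
# promoter driving the cassette); survivors are ranked by off-target count,
# PAM-codon distance, 4-bp-seed purine content and guide GC range, then the
# top k per codon swap are kept.

#' polyT filter predicate
#'
#' @param x Sequence of the transcribed cassette (donor + guide; assembly
#'   adapters are excluded from the scan).
#' @return `TRUE` iff `x` contains `TTTTT` (five or more consecutive T's).
#' @export
has_polyT <- function(x) grepl("TTTTT", x, fixed = TRUE)

#' Purine (A+G) fraction of the 4-bp seed
#'
#' @param seed4 The PAM-proximal 4-mer of a guide.
#' @return Fraction in `[0, 1]`.
#' @export
seed_purine_fraction <- function(seed4) {
  if (any(nchar(seed4) != 4L)) stop("seed4 must be a 4-mer")
  nchar(gsub("[^AG]", "", dna(seed4))) / 4
}

#' Is a guide's GC content inside the preferred range?
#'
#' The 30-80% range is inclusive at both boundaries.
#'
#' @param gc GC fraction of a 20-mer guide.
#' @param lo,hi Range boundaries (fractions).
#' @return Logical.
#' @export
gc_in_range <- function(gc, lo = 0.30, hi = 0.80) gc >= lo & gc <= hi

# ---- Seed index ------------------------------------------------------------

#' Build a genome-wide 12-bp seed index
#'
#' Indexes, on both strands, every k-mer that sits immediately 5' of a
#' PAM matching `pam_pattern` (a hit without an adjacent PAM is not a
#' cleavable site and is not indexed). K-mers containing `N` are skipped.
#' The stored `offset` is the 0-based plus-strand start of the k-mer
#' window regardless of strand.
#'
#' @param genome Named character vector of sequences (or a FASTA path).
#' @param k Seed length (default 12).
#' @param pam_pattern IUPAC 3-mer required adjacent to each indexed k-mer.
#' @return Object of class `seed_index`.
#' @export
build_seed_index <- function(genome, k = 12L, pam_pattern = "NGN") {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    genome <- read_fasta(genome)
  }
  if (any(nchar(genome) == 0L)) stop("empty sequence in genome")
  per_seq <- lapply(names(genome), function(id) {
    s <- genome[[id]]
    L <- nchar(s)
    out <- list()
    if (L >= k + 3L) {
      # plus strand: kmer at [i, i+k), PAM at [i+k, i+k+3)
      i <- seq.int(0L, L - k - 3L)
      kmer <- substring(s, i + 1L, i + k)
      pam <- substring(s, i + k + 1L, i + k + 3L)
      keep <- matches_iupac(pam, pam_pattern) & !grepl("N", kmer, fixed = TRUE)
      out$p <- data.table::data.table(kmer = kmer[keep], seq_id = id,
                                      offset = i[keep], strand = "+")
      # minus strand: PAM at [j, j+3) on plus, kmer window [j+3, j+3+k)
      j <- seq.int(0L, L - k - 3L)
      kmer_m <- reverse_complement(substring(s, j + 4L, j + 3L + k))
      pam_m <- reverse_complement(substring(s, j + 1L, j + 3L))
      keep <- matches_iupac(pam_m, pam_pattern) &
        !grepl("N", kmer_m, fixed = TRUE)
      out$m <- data.table::data.table(kmer = kmer_m[keep], seq_id = id,
                                      offset = j[keep] + 3L, strand = "-")
    }
    data.table::rbindlist(out)
  })
  tab <- data.table::rbindlist(per_seq)
  if (nrow(tab) == 0L) {
    tab <- data.table::data.table(kmer = character(0), seq_id = character(0),
                                  offset = integer(0), strand = character(0))
  }
  data.table::setkey(tab, kmer)
  structure(list(k = as.integer(k), pam_pattern = pam_pattern, table = tab),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("<seed_index> k=", x$k, ", PAM ", x$pam_pattern, ", ",
      nrow(x$table), " indexed positions\n", sep = "")
  invisible(x)
}

#' Exact-match hits of a seed in the index
#'
#' @param index A [build_seed_index()] result.
#' @param seed k-mer to look up.
#' @return data.frame of `(seq_id, offset, strand)` hits.
#' @export
seed_hits <- function(index, seed) {
  if (nchar(seed) != index$k) stop("seed length != index k")
  hits <- index$table[data.table::data.table(kmer = seed), nomatch = NULL]
  as.data.frame(hits[, c("seq_id", "offset", "strand")])
}

#' Count 12-bp seed off-targets for a guide
#'
#' Number of genomic positions whose PAM-adjacent k-mer equals the guide's
#' PAM-proximal seed, excluding the on-target occurrence.
#'
#' @param index A [build_seed_index()].
#' @param guide A [guide_for_pam()] result (its `seed12` is looked up).
#' @param on_target Optional list/row `(seq_id, offset, strand)` giving the
#'   on-target seed window location inside the indexed genome. When
#'   supplied it must be present in the index (else a consistency error is
#'   raised) and is subtracted from the count; when `NULL` the design
#'   context is assumed absent from the genome and all hits count.
#' @return Non-negative integer.
#' @export
count_offtargets <- function(index, guide, on_target = NULL) {
  hits <- seed_hits(index, guide$seed12)
  if (is.null(on_target)) return(nrow(hits))
  is_on <- hits$seq_id == on_target$seq_id &
    hits$offset == on_target$offset & hits$strand == on_target$strand
  if (!any(is_on)) {
    stop("on-target seed not found in index (", on_target$seq_id, ":",
         on_target$offset, on_target$strand, ")")
  }
  nrow(hits) - sum(is_on)
}

#' Serialize / load a seed index as TSV
#'
#' @param index A `seed_index`.
#' @param path TSV path (columns kmer, seq_id, offset, strand).
#' @return `path` / a `seed_index`.
#' @export
write_seed_index <- function(index, path) {
  data.table::fwrite(index$table, path, sep = "\t")
  invisible(path)
}

#' @rdname write_seed_index
#' @param k,pam_pattern Metadata restored alongside the table.
#' @export
read_seed_index <- function(path, k = 12L, pam_pattern = "NGN") {
  tab <- data.table::fread(path, sep = "\t",
                           colClasses = list(character = c("kmer", "seq_id",
                                                           "strand"),
                                             integer = "offset"))
  data.table::setkey(tab, kmer)
  structure(list(k = as.integer(k), pam_pattern = pam_pattern, table = tab),
            class = "seed_index")
}

#' Seed-only partial-match scan (no PAM requirement)
#'
#' Finds genomic windows whose PAM-proximal end matches at least
#' `min_match` contiguous bases of the seed's PAM-proximal (3') end, on
#' either strand. This is the looser, BLAST-like off-target survey mode;
#' unlike [count_offtargets()] no adjacent PAM is required.
#'
#' @param genome Named character vector of sequences.
#' @param seed12 12-mer seed.
#' @param min_match Minimum contiguous PAM-proximal match (10-12).
#' @return data.frame `(seq_id, offset, strand, match_len)`, where
#'   `offset` is the plus-strand start of the 12-base window and
#'   `match_len` the maximal contiguous PAM-proximal match length.
#' @export
find_seed_matches <- function(genome, seed12, min_match = 10L) {
  if (nchar(seed12) != 12L) stop("seed12 must be a 12-mer")
  if (min_match < 10L || min_match > 12L) stop("min_match must be in 10..12")
  k <- 12L
  out <- lapply(names(genome), function(id) {
    s <- genome[[id]]
    L <- nchar(s)
    if (L < k) return(NULL)
    i <- seq.int(0L, L - k)
    res <- list()
    for (strand in c("+", "-")) {
      win <- substring(s, i + 1L, i + k)
      if (strand == "-") win <- reverse_complement(win)
      # contiguous match length measured from the 3' (PAM-proximal) end
      mlen <- integer(length(win))
      alive <- rep(TRUE, length(win))
      for (m in seq_len(k)) {
        pos <- k - m + 1L
        alive <- alive & substring(win, pos, pos) == substring(seed12, pos, pos)
        mlen[alive] <- m
      }
      keep <- mlen >= min_match
      if (any(keep)) {
        res[[strand]] <- data.frame(seq_id = id, offset = i[keep],
                                    strand = strand, match_len = mlen[keep],
                                    stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), match_len = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# ---- Ranking and selection -------------------------------------------------

# Rank-feature data.frame for a list of cassettes.
rank_features <- function(cassettes) {
  data.frame(
    offtargets = vapply(cassettes, function(x) x$offtargets, numeric(1)),
    distance = vapply(cassettes, function(x) x$distance, numeric(1)),
    seed4_purine = vapply(cassettes, function(x) x$seed4_purine, numeric(1)),
    gc_in_range = vapply(cassettes, function(x) x$gc_in_range, logical(1)),
    offset = vapply(cassettes, function(x) x$pam$offset, numeric(1)),
    strand = vapply(cassettes, function(x) x$pam$strand, character(1))
  )
}

#' Rank candidate cassettes for one codon swap and keep the top k
#'
#' polyT-carrying candidates are removed first. Survivors are ordered
#' lexicographically by: off-target count ascending, PAM-codon distance
#' ascending, seed purine fraction descending, in-range GC before
#' out-of-range, then `(PAM offset, strand)` as a deterministic tie-break.
#' The first `k` get ranks `0..k-1`.
#'
#' Candidates carrying identical substitution sets describe the same edited
#' allele (the codon edit alone destroyed cleavability for several guides);
#' since each library cassette must correspond to a unique genetic variant,
#' only the best-ranked cassette per substitution set is kept.
#'
#' @param cassettes List of candidate cassettes for one (codon, new codon).
#' @param k Cassettes to keep (default 4).
#' @param strict_gc Treat out-of-range GC as a hard filter, not a rank key.
#' @param exclude_variants Variant keys (as produced by
#'   [cassette_variant_key()]) already claimed elsewhere in the library;
#'   candidates matching one are skipped.
#' @return The selected cassettes (possibly fewer than `k`, or none) with
#'   `$rank` set.
#' @export
rank_and_select <- function(cassettes, k = 4L, strict_gc = FALSE,
                            exclude_variants = character(0)) {
  if (!length(cassettes)) return(list())
  keep <- !vapply(cassettes, function(x) has_polyT(x$core), logical(1))
  cassettes <- cassettes[keep]
  if (strict_gc && length(cassettes)) {
    cassettes <- cassettes[vapply(cassettes, function(x) x$gc_in_range,
                                  logical(1))]
  }
  if (!length(cassettes)) return(list())
  f <- rank_features(cassettes)
  ord <- order(f$offtargets, f$distance, -f$seed4_purine, !f$gc_in_range,
               f$offset, f$strand == "-")
  ranked <- cassettes[ord]
  variant <- vapply(ranked, cassette_variant_key, character(1))
  ranked <- ranked[!duplicated(variant) & !(variant %in% exclude_variants)]
  sel <- ranked[seq_len(min(k, length(ranked)))]
  for (i in seq_along(sel)) sel[[i]]$rank <- i - 1L
  sel
}

#' Variant key of a cassette
#'
#' Canonical string identifying the edited allele (offsets and alternate
#' bases of all substitutions). Two cassettes with equal keys produce the
#' same genetic variant.
#'
#' @param cassette A cassette list.
#' @return Character scalar.
#' @export
cassette_variant_key <- function(cassette) {
  s <- cassette$substitutions
  paste(s$offset, s$alt, sep = ":", collapse = ",")
}
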
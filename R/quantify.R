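# Amplicon-NGS quantification of editing outcomes. Merged reads are
# filtered (primers at both ends, exact reference length: a
# substitution-only model), oriented, compared position-by-position to the
# segment reference, and the observed mismatch set is matched against the
# designed library. Counts are normalized to reads-per-million per segment.

#' Define amplicon segments over a gene target
#'
#' Splits a context region into amplicons and derives primers from their
#' ends. References are wild-type context substrings, so each begins with
#' its forward primer and ends with the reverse complement of its reverse
#' primer.
#'
#' @param target A [gene_target()].
#' @param intervals List of 0-based half-open context intervals, one per
#'   segment.
#' @param primer_len Primer length (default 20).
#' @param ids Optional segment ids (default `seg1..segN`).
#' @return data.frame with columns `segment_id`, `fwd_primer`,
#'   `rev_primer`, `context_offset`, `reference`.
#' @export
amplicon_segments <- function(target, intervals, primer_len = 20L,
                              ids = NULL) {
  if (is.null(ids)) ids <- paste0("seg", seq_along(intervals))
  rows <- lapply(seq_along(intervals), function(i) {
    iv <- intervals[[i]]
    ref <- substr(target$context, iv[1] + 1L, iv[2])
    if (nchar(ref) < 2L * primer_len) stop("segment shorter than primers")
    data.frame(segment_id = ids[i],
               fwd_primer = substr(ref, 1L, primer_len),
               rev_primer = reverse_complement(
                 substr(ref, nchar(ref) - primer_len + 1L, nchar(ref))),
               context_offset = as.integer(iv[1]),
               reference = ref, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read a segments table
#' @param segments data.frame as from [amplicon_segments()].
#' @param path TSV path.
#' @return `path` / the segments data.frame.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", stringsAsFactors = FALSE) |>
    transform(context_offset = as.integer(context_offset))
}

#' Minimal exact-overlap merger for paired-end reads
#'
#' Convenience stand-in for a dedicated merging tool: scans overlap lengths
#' between read 1 and the reverse complement of read 2, scores mismatches,
#' and keeps the longest overlap passing both thresholds. At mismatching
#' overlap positions the higher-quality base wins.
#'
#' @param r1,r2 Single reads as lists/rows with `seq` and `qual`.
#' @param min_overlap Minimum acceptable overlap length.
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return List with `seq` and `qual` of the merged read, or `NULL` when
#'   no overlap passes.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20L, max_mismatch_frac = 0.1) {
  if (nchar(r1$seq) != nchar(r1$qual) || nchar(r2$seq) != nchar(r2$qual)) {
    stop("sequence/quality length mismatch")
  }
  s2 <- reverse_complement(r2$seq)
  q2 <- paste(rev(strsplit(r2$qual, "", fixed = TRUE)[[1]]), collapse = "")
  n1 <- nchar(r1$seq); n2 <- nchar(s2)
  a <- strsplit(r1$seq, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  qa <- utf8ToInt(r1$qual); qb <- utf8ToInt(q2)
  for (ov in seq.int(min(n1, n2), min_overlap)) {
    x <- a[(n1 - ov + 1L):n1]; y <- b[1:ov]
    mm <- which(x != y)
    if (length(mm) / ov > max_mismatch_frac) next
    cons <- x
    if (length(mm)) {
      qx <- qa[(n1 - ov + 1L):n1][mm]; qy <- qb[1:ov][mm]
      cons[mm] <- ifelse(qy > qx, y[mm], x[mm])
    }
    merged_seq <- paste0(substr(r1$seq, 1L, n1 - ov),
                         paste(cons, collapse = ""),
                         substr(s2, ov + 1L, n2))
    qcons <- pmax(qa[(n1 - ov + 1L):n1], qb[1:ov])
    merged_qual <- paste0(substr(r1$qual, 1L, n1 - ov),
                          intToUtf8(qcons, multiple = FALSE),
                          substr(q2, ov + 1L, n2))
    return(list(seq = merged_seq, qual = merged_qual))
  }
  NULL
}

#' Filter and orient merged reads against one segment
#'
#' A read is retained iff (after orientation) it begins with the forward
#' primer, ends with the reverse complement of the reverse primer, and has
#' exactly the reference length (substitution-only model: any InDel is
#' rejected as `filtered_length`).
#'
#' @param reads Character vector of merged read sequences.
#' @param segment One row of a segments table.
#' @return List with `seq` (oriented retained reads), `status` (per input
#'   read: `retained`, `filtered_primer` or `filtered_length`) and `idx`
#'   (input indices of the retained reads).
#' @export
filter_and_orient <- function(reads, segment) {
  reads <- dna(reads)
  fwd <- segment$fwd_primer
  tail3 <- reverse_complement(segment$rev_primer)
  ref_len <- nchar(segment$reference)
  oriented <- reads
  flip <- !startsWith(reads, fwd)
  if (any(flip)) oriented[flip] <- reverse_complement(reads[flip])
  has_primers <- startsWith(oriented, fwd) & endsWith(oriented, tail3)
  right_len <- nchar(oriented) == ref_len
  status <- rep("retained", length(reads))
  status[!has_primers] <- "filtered_primer"
  status[has_primers & !right_len] <- "filtered_length"
  keep <- status == "retained"
  list(seq = oriented[keep], status = status, idx = which(keep))
}

# Mismatch set of an oriented read vs its segment reference, as context
# coordinates ("offset:REF>ALT" keys).
observed_substitutions <- function(read, segment) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  ref <- strsplit(segment$reference, "", fixed = TRUE)[[1]]
  d <- which(r != ref)
  data.frame(offset = segment$context_offset + d - 1L, ref = ref[d],
             alt = r[d], stringsAsFactors = FALSE)
}

sub_keys <- function(subs) {
  if (nrow(subs) == 0L) return(character(0))
  sort(sprintf("%d:%s>%s", subs$offset, subs$ref, subs$alt))
}

# Designed substitution sets restricted to a segment, as key-string vectors
# per cassette. Cassettes with no designed base inside the segment are
# dropped; duplicated restricted sets are a library-integrity error.
segment_design_sets <- function(library, segment) {
  lo <- segment$context_offset
  hi <- lo + nchar(segment$reference)
  sets <- lapply(seq_len(nrow(library)), function(i) {
    subs <- parse_substitutions(library$substitutions[i])
    subs <- subs[subs$offset >= lo & subs$offset < hi, , drop = FALSE]
    sub_keys(subs)
  })
  names(sets) <- library$id
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  joined <- vapply(sets, paste, character(1), collapse = ",")
  if (anyDuplicated(joined)) {
    dup <- names(sets)[duplicated(joined) | duplicated(joined,
                                                       fromLast = TRUE)]
    stop("cassettes with identical substitution sets within segment '",
         segment$segment_id, "': ", paste(dup, collapse = ", "))
  }
  sets
}

#' Call the editing outcome of one oriented read
#'
#' The read's mismatch set against the reference is compared with each
#' cassette's designed substitutions restricted to the segment: exact set
#' equality is a `perfect` call; a non-empty proper subset of exactly this
#' design space is `imperfect` (partial HDR); no mismatches is
#' `wild_type`; any mismatch at a position/base no cassette designs is
#' `unmatched` (sequencing error or unplanned variant).
#'
#' @param read Oriented read sequence (already past [filter_and_orient()]).
#' @param segment One segment row.
#' @param design_sets Result of `segment_design_sets()` for this segment
#'   (precomputed by [count_and_normalize()]).
#' @return List with `status` and `cassette_id` (NA unless perfect) and
#'   `observed` (key strings).
#' @export
call_edit <- function(read, segment, design_sets,
                      full_keys = vapply(design_sets, paste, character(1),
                                         collapse = ",")) {
  obs <- sub_keys(observed_substitutions(read, segment))
  if (length(obs) == 0L) {
    return(list(status = "wild_type", cassette_id = NA_character_,
                observed = obs))
  }
  obs_key <- paste(obs, collapse = ",")
  hit <- names(full_keys)[full_keys == obs_key]
  if (length(hit) == 1L) {
    return(list(status = "perfect", cassette_id = hit, observed = obs))
  }
  is_subset <- vapply(design_sets, function(s) all(obs %in% s), logical(1))
  if (any(is_subset)) {
    return(list(status = "imperfect", cassette_id = NA_character_,
                observed = obs))
  }
  list(status = "unmatched", cassette_id = NA_character_, observed = obs)
}

#' Count designed edits in merged reads and normalize per segment
#'
#' Runs [filter_and_orient()] and [call_edit()] over every read/segment,
#' then normalizes: `normalized = raw * 1e6 / total retained reads of the
#' segment`. Reads are assigned to the first segment whose primers they
#' carry.
#'
#' @param reads Character vector of merged read sequences (or a
#'   [read_fastq()] data.frame).
#' @param segments Segments table.
#' @param library Library manifest data.frame ([read_library_manifest()]).
#' @return Object of class `count_table`: list with `cassettes` (raw and
#'   normalized counts per cassette), `statuses` (per segment tallies of
#'   every call status plus filtered reads), `segments` (totals; a segment
#'   with zero retained reads has `normalized_defined = FALSE`), and
#'   `calls` (per-read assignments).
#' @export
count_and_normalize <- function(reads, segments, library) {
  if (is.data.frame(reads)) reads <- reads$seq
  reads <- dna(reads)
  design_sets <- lapply(seq_len(nrow(segments)), function(i)
    segment_design_sets(library, segments[i, ]))
  n <- length(reads)
  read_status <- rep("filtered_primer", n)
  read_segment <- rep(NA_character_, n)
  read_cassette <- rep(NA_character_, n)
  assigned <- rep(FALSE, n)
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    todo <- which(!assigned)
    if (!length(todo)) break
    fo <- filter_and_orient(reads[todo], seg)
    # a read belongs to this segment when its primers match (either status
    # retained or filtered_length with both primers present)
    belongs <- fo$status != "filtered_primer"
    read_segment[todo[belongs]] <- seg$segment_id
    read_status[todo[belongs]] <- fo$status[belongs]
    assigned[todo[belongs]] <- TRUE
    if (length(fo$idx)) {
      full_keys <- vapply(design_sets[[i]], paste, character(1),
                          collapse = ",")
      # most retained reads are wild type or exact repeats: call each
      # distinct sequence once
      uniq <- unique(fo$seq)
      calls_u <- lapply(uniq, call_edit, segment = seg,
                        design_sets = design_sets[[i]],
                        full_keys = full_keys)
      m <- match(fo$seq, uniq)
      gi <- todo[fo$idx]
      read_status[gi] <- vapply(calls_u, `[[`, character(1), "status")[m]
      read_cassette[gi] <- vapply(calls_u, `[[`, character(1),
                                  "cassette_id")[m]
    }
  }
  calls <- data.frame(read = seq_len(n), segment = read_segment,
                      status = read_status, cassette_id = read_cassette,
                      stringsAsFactors = FALSE)
  seg_rows <- list(); cas_rows <- list(); status_rows <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    in_seg <- calls$segment %in% seg$segment_id
    retained_status <- c("wild_type", "perfect", "imperfect", "unmatched")
    total <- sum(in_seg & calls$status %in% retained_status)
    seg_rows[[i]] <- data.frame(segment_id = seg$segment_id,
                                total_retained = total,
                                total_assigned = sum(in_seg),
                                normalized_defined = total > 0L,
                                stringsAsFactors = FALSE)
    st <- table(factor(calls$status[in_seg],
                       levels = c(retained_status, "filtered_length")))
    st_norm <- ifelse(names(st) %in% retained_status & total > 0L,
                      as.integer(st) * 1e6 / total, NA_real_)
    status_rows[[i]] <- data.frame(segment_id = seg$segment_id,
                                   status = names(st),
                                   raw = as.integer(st),
                                   normalized = st_norm,
                                   stringsAsFactors = FALSE)
    ids <- names(design_sets[[i]])
    tab <- table(calls$cassette_id[in_seg])
    raw <- as.integer(tab[ids])
    raw[is.na(raw)] <- 0L
    cas_rows[[i]] <- data.frame(cassette_id = ids, segment_id =
                                  seg$segment_id, raw = as.integer(raw),
                                normalized = if (total > 0L)
                                  raw * 1e6 / total else NA_real_,
                                stringsAsFactors = FALSE)
  }
  structure(list(cassettes = do.call(rbind, cas_rows),
                 statuses = do.call(rbind, status_rows),
                 segments = do.call(rbind, seg_rows),
                 calls = calls),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$segments), " segments, ",
      sum(x$cassettes$raw), " perfect cassette reads\n", sep = "")
  invisible(x)
}

#' Per-codon and library-level saturation summary
#'
#' A codon counts as edited when at least one of its cassettes has a
#' perfect call; redundancy is the number of distinct perfect cassettes
#' observed at that codon. Library-level percentages are reported for all
#' cassettes and broken down by category (synonymous / missense / stop),
#' both per designed cassette and per designed amino-acid swap.
#'
#' @param counts A [count_and_normalize()] result.
#' @param library Library manifest data.frame.
#' @return List with `per_codon` (data.frame) and `overall` (data.frame of
#'   category, designed/observed cassette and swap counts and
#'   percentages).
#' @export
saturation_summary <- function(counts, library) {
  obs <- counts$cassettes[counts$cassettes$raw > 0L, , drop = FALSE]
  observed_ids <- unique(obs$cassette_id)
  lib <- library
  lib$observed <- lib$id %in% observed_ids
  codons <- sort(unique(lib$codon_index))
  per_codon <- do.call(rbind, lapply(codons, function(ci) {
    sub <- lib[lib$codon_index == ci, , drop = FALSE]
    nobs <- sum(sub$observed)
    data.frame(codon_index = ci, designed = nrow(sub),
               observed_cassettes = nobs, edited = nobs >= 1L,
               redundancy = nobs,
               synonymous = sum(sub$observed & sub$category == "synonymous"),
               missense = sum(sub$observed & sub$category == "missense"),
               stop = sum(sub$observed & sub$category == "stop"))
  }))
  swap_key <- paste(lib$codon_index, lib$new_codon)
  cat_stats <- function(mask) {
    d_cas <- sum(mask); o_cas <- sum(mask & lib$observed)
    d_swap <- length(unique(swap_key[mask]))
    o_swap <- length(unique(swap_key[mask & lib$observed]))
    c(designed_cassettes = d_cas, observed_cassettes = o_cas,
      pct_cassettes_observed = if (d_cas) 100 * o_cas / d_cas else NA,
      designed_swaps = d_swap, observed_swaps = o_swap,
      pct_swaps_observed = if (d_swap) 100 * o_swap / d_swap else NA)
  }
  cats <- c("all", "synonymous", "missense", "stop")
  overall <- do.call(rbind, lapply(cats, function(cc) {
    mask <- if (cc == "all") rep(TRUE, nrow(lib)) else lib$category == cc
    as.data.frame(as.list(cat_stats(mask)))
  }))
  overall <- cbind(category = cats, overall)
  list(per_codon = per_codon, overall = overall,
       pct_codons_edited = 100 * mean(per_codon$edited),
       pct_codons_redundant = 100 * mean(per_codon$redundancy >= 2L))
}
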
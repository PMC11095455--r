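# Synthetic fixtures: toy genes with planted sequence features, and edited
# amplicon reads at controlled abundances and substitution-error rates.
# Everything is seeded, so fixed inputs give byte-identical outputs.

#' Generate a toy gene target
#'
#' Random context with an in-frame ORF (ATG start, no internal stop,
#' terminal TAA) and optional features planted verbatim at recorded
#' offsets. Useful features include PAM deserts (G/C-free stretches),
#' duplicated guide seeds, and polyT traps.
#'
#' @param orf_codons Total ORF codons including start and stop (>= 5).
#' @param flank Flank length on each side (default 80, enough for arm +
#'   guide + PAM reach).
#' @param gc_bias Marginal G+C probability per random base.
#' @param seed RNG seed.
#' @param planted List of `list(offset, seq)` features, 0-based context
#'   offsets, injected after random generation (overlapping features are a
#'   construction error).
#' @param gene_id Identifier.
#' @return A [gene_target()].
#' @export
make_toy_gene <- function(orf_codons = 30L, flank = 80L, gc_bias = 0.40,
                          seed = 1L, planted = list(), gene_id = "toy") {
  if (orf_codons < 5L) stop("orf_codons must be >= 5")
  if (gc_bias <= 0 || gc_bias >= 1) stop("gc_bias must be in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2, G = gc_bias / 2,
         T = (1 - gc_bias) / 2)
  rand <- function(n) paste(sample(names(p), n, replace = TRUE, prob = p),
                            collapse = "")
  sense_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))
  body <- paste(sample(sense_codons, orf_codons - 2L, replace = TRUE),
                collapse = "")
  context <- paste0(rand(flank), "ATG", body, "TAA", rand(flank))
  if (length(planted)) {
    ivs <- lapply(planted, function(f) c(f$offset, f$offset + nchar(f$seq)))
    ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 1L))]
    for (i in seq_along(ivs)[-1]) {
      if (ivs[[i]][1] < ivs[[i - 1]][2]) stop("planted features overlap")
    }
    for (f in planted) {
      if (f$offset < 0L || f$offset + nchar(f$seq) > nchar(context)) {
        stop("planted feature outside context")
      }
      substr(context, f$offset + 1L, f$offset + nchar(f$seq)) <- dna(f$seq)
    }
  }
  gene_target(gene_id, context, orf_start = flank,
              orf_length = 3L * orf_codons)
}

#' Simulate merged amplicon reads from a designed library
#'
#' For each requested read, the genotype's substitutions are applied to
#' its segment reference, substitution errors are injected at `error_rate`
#' per base, and the read is reverse-complemented with probability 0.5.
#' Abundances are exact counts by default so round-trip tests are exact;
#' `multinomial = TRUE` resamples them multinomially at the same total.
#'
#' @param library Library manifest data.frame.
#' @param segments Segments table.
#' @param abundances Named integer vector: reads per cassette id, plus
#'   optionally `WT` for wild-type reads (replicated across segments).
#'   Each cassette is simulated from the first segment containing all its
#'   designed substitutions.
#' @param error_rate Per-base substitution error probability (0-0.2).
#' @param seed RNG seed.
#' @param multinomial Resample abundances multinomially.
#' @return data.frame of reads (`id`, `seq`, `qual`) with the true
#'   genotype encoded in the read id.
#' @export
simulate_reads <- function(library, segments, abundances, error_rate = 0,
                           seed = 1L, multinomial = FALSE) {
  if (error_rate < 0 || error_rate > 0.2) stop("error_rate must be in [0, 0.2]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- names(abundances)
  unknown <- setdiff(setdiff(ids, "WT"), library$id)
  if (length(unknown)) stop("abundances reference unknown cassette ids: ",
                            paste(unknown, collapse = ", "))
  if (multinomial) {
    n <- sum(abundances)
    abundances <- stats::setNames(
      as.integer(stats::rmultinom(1L, n, abundances / n)), ids)
  }
  # a usable segment must contain every designed substitution outside its
  # primer windows (an edit inside a primer cannot be amplified/sequenced)
  seg_for_cassette <- function(id) {
    subs <- parse_substitutions(library$substitutions[library$id == id])
    for (i in seq_len(nrow(segments))) {
      lo <- segments$context_offset[i] + nchar(segments$fwd_primer[i])
      hi <- segments$context_offset[i] + nchar(segments$reference[i]) -
        nchar(segments$rev_primer[i])
      if (all(subs$offset >= lo & subs$offset < hi)) return(i)
    }
    stop("no single segment contains all substitutions of ", id,
         " outside its primer windows")
  }
  alphabet <- c("A", "C", "G", "T")
  out_id <- character(0); out_seq <- character(0)
  emit <- function(genotype, seg_i, count) {
    if (count <= 0L) return()
    seg <- segments[seg_i, ]
    ref_ch <- strsplit(seg$reference, "", fixed = TRUE)[[1]]
    base_ch <- ref_ch
    if (genotype != "WT") {
      subs <- parse_substitutions(
        library$substitutions[library$id == genotype])
      local_off <- subs$offset - seg$context_offset
      stopifnot(all(base_ch[local_off + 1L] == subs$ref))
      base_ch[local_off + 1L] <- subs$alt
    }
    L <- length(base_ch)
    seqs <- if (error_rate == 0) {
      rep(paste(base_ch, collapse = ""), count)
    } else {
      vapply(seq_len(count), function(r) {
        ch <- base_ch
        hit <- which(stats::runif(L) < error_rate)
        for (i in hit) ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
        paste(ch, collapse = "")
      }, character(1))
    }
    flip <- stats::runif(count) < 0.5
    if (any(flip)) seqs[flip] <- reverse_complement(seqs[flip])
    out_id <<- c(out_id, sprintf("%s|%s|%d", genotype, seg$segment_id,
                                 seq_len(count)))
    out_seq <<- c(out_seq, seqs)
  }
  for (id in ids) {
    if (id == "WT") {
      for (i in seq_len(nrow(segments))) emit("WT", i, abundances[[id]])
    } else {
      emit(id, seg_for_cassette(id), abundances[[id]])
    }
  }
  data.frame(id = out_id, seq = out_seq, qual = strrep("I", nchar(out_seq)),
             stringsAsFactors = FALSE)
}
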
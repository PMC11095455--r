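# Independent brute-force oracles used by the property tests. These are
# deliberately naive (character loops, no reuse of package internals) so
# they stay independent of the code paths they check.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_pam_match <- function(triplet, pattern) {
  tc <- strsplit(triplet, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  all(vapply(1:3, function(i) tc[i] %in% oracle_iupac_sets[[pc[i]]],
             logical(1)))
}

# All PAM sites on both strands, by direct loop.
oracle_scan_pams <- function(context, pattern) {
  L <- nchar(context)
  res <- list()
  for (o in 0:(L - 3)) {
    tri <- substr(context, o + 1, o + 3)
    if (oracle_pam_match(tri, pattern)) {
      res[[length(res) + 1]] <- data.frame(offset = o, strand = "+",
                                           pam_seq = tri)
    }
    rc <- oracle_revcomp(tri)
    if (oracle_pam_match(rc, pattern)) {
      res[[length(res) + 1]] <- data.frame(offset = o, strand = "-",
                                           pam_seq = rc)
    }
  }
  do.call(rbind, res)
}

# Genome-wide exact seed+PAM occurrence count, by direct loop.
oracle_count_seed <- function(genome, seed, pattern) {
  k <- nchar(seed)
  n <- 0L
  for (id in names(genome)) {
    s <- genome[[id]]
    L <- nchar(s)
    if (L < k + 3) next
    for (i in 0:(L - k - 3)) {
      if (substr(s, i + 1, i + k) == seed &&
          oracle_pam_match(substr(s, i + k + 1, i + k + 3), pattern)) {
        n <- n + 1L
      }
      win <- oracle_revcomp(substr(s, i + 4, i + 3 + k))
      pam <- oracle_revcomp(substr(s, i + 1, i + 3))
      if (win == seed && oracle_pam_match(pam, pattern)) n <- n + 1L
    }
  }
  n
}

random_genome <- function(len, seed, ids = "chr1") {
  set.seed(seed)
  out <- vapply(ids, function(id)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  out
}

# Small shared fixtures -----------------------------------------------------

toy_gene <- function(...) make_toy_gene(...)

# A gene + k=2 NGN saturation library + single whole-context segment,
# reused by quantification tests. Designs are cached per parameter set so
# repeated tests do not redo the (deterministic) design work.
.fixture_cache <- new.env(parent = emptyenv())
toy_design_fixture <- function(orf_codons = 15L, seed = 11L, k = 2L,
                               pam = "NGN") {
  key <- paste(orf_codons, seed, k, pam, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  tg <- make_toy_gene(orf_codons = orf_codons, seed = seed)
  lib <- design_saturation_library(tg, design_spec(pam_pattern = pam, k = k))
  man <- library_manifest(lib)
  segs <- amplicon_segments(tg, list(c(0L, nchar(tg$context))))
  .fixture_cache[[key]] <- list(target = tg, lib = lib, man = man,
                                segs = segs)
  .fixture_cache[[key]]
}
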
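# Codon usage machinery. Representative codons default to the most frequent
# S. cerevisiae codon per amino acid (Kazusa usage table, per-1000 counts);
# the ranked lists drive the synonymous-design fallback when the top codon
# equals the wild-type codon. Both are overridable through codon_table().

# Synonymous codons per amino acid, ranked by S. cerevisiae usage
# (most frequent first; ties broken alphabetically).
.YEAST_CODON_RANKS <- list(
  A = c("GCT", "GCA", "GCC", "GCG"),
  R = c("AGA", "AGG", "CGT", "CGA", "CGC", "CGG"),
  N = c("AAT", "AAC"),
  D = c("GAT", "GAC"),
  C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"),
  E = c("GAA", "GAG"),
  G = c("GGT", "GGA", "GGC", "GGG"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATA", "ATC"),
  L = c("TTG", "TTA", "CTA", "CTT", "CTG", "CTC"),
  K = c("AAA", "AAG"),
  M = "ATG",
  F = c("TTT", "TTC"),
  P = c("CCA", "CCT", "CCC", "CCG"),
  S = c("TCT", "TCA", "TCC", "AGT", "AGC", "TCG"),
  T = c("ACT", "ACA", "ACC", "ACG"),
  W = "TGG",
  Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG"),
  `*` = c("TAA", "TAG", "TGA")
)

#' Codon table for library design
#'
#' Bundles the standard nuclear genetic code with a per-amino-acid ranked
#' list of design codons and a stop codon. Saturation designs replace each
#' target codon with the representative (top-ranked) codon of every amino
#' acid; the synonymous design for the wild-type amino acid falls back to
#' the highest-ranked codon that differs from the wild-type codon.
#'
#' @param ranks Named list (20 amino acids plus `*`) of synonymous codons,
#'   most preferred first. Defaults to S. cerevisiae usage order.
#' @param stop_codon Stop codon used by stop-scan and saturation designs.
#' @return Object of class `codon_table`.
#' @export
codon_table <- function(ranks = .YEAST_CODON_RANKS, stop_codon = "TAA") {
  code <- Biostrings::GENETIC_CODE
  for (aa in names(ranks)) {
    tr <- unname(code[ranks[[aa]]])
    if (!all(tr == aa)) {
      stop("ranked codons for '", aa, "' do not all translate to it")
    }
  }
  if (unname(code[stop_codon]) != "*") stop(stop_codon, " is not a stop codon")
  representative <- vapply(ranks, `[`, character(1), 1L)
  structure(list(code = code, ranks = ranks,
                 representative = representative, stop_codon = stop_codon),
            class = "codon_table")
}

#' Synonymous codons of a codon
#'
#' @param ct A [codon_table()].
#' @param codon 3-mer.
#' @param exclude_self Drop `codon` itself from the result.
#' @return Character vector of codons with identical translation, in rank
#'   order.
#' @export
synonymous_codons <- function(ct, codon, exclude_self = TRUE) {
  aa <- unname(ct$code[codon])
  if (is.na(aa)) stop("unknown codon: ", codon)
  syn <- ct$ranks[[aa]]
  if (is.null(syn)) syn <- names(ct$code)[ct$code == aa]
  if (exclude_self) syn <- setdiff(syn, codon)
  syn
}

#' New codon for one (wild-type codon, target class) pair
#'
#' `NA` when no codon change exists (the synonymous class at a
#' single-codon amino acid, Met/Trp).
#'
#' @param ct A [codon_table()].
#' @param wt_codon Wild-type 3-mer.
#' @param class One of the 20 amino acids or `"*"`.
#' @return A 3-mer or `NA`.
#' @export
design_codon_for_class <- function(ct, wt_codon, class) {
  wt_aa <- unname(ct$code[wt_codon])
  new_codon <- if (class == "*") ct$stop_codon else ct$representative[[class]]
  if (new_codon == wt_codon) {
    alt <- synonymous_codons(ct, wt_codon)
    new_codon <- if (length(alt)) alt[1L] else NA_character_
  }
  new_codon
}

#' The 21 target classes of saturation mode: the 20 amino acids then stop
#' @return Character vector of length 21.
#' @export
saturation_classes <- function() c(setdiff(names(.YEAST_CODON_RANKS), "*"), "*")
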
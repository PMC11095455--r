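# Sequence model, codon machinery and FASTA/FASTQ I/O shared by the design
# and quantification modules. Coordinates are 0-based half-open throughout;
# codon numbering is 1-based with codon 1 = the start codon.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate and normalize a DNA sequence
#'
#' Uppercases the input and checks that every character is one of A, C, G,
#' T or N. All package functions call this on ingestion so that internal
#' sequences are guaranteed to be normalized.
#'
#' @param x Character vector of sequences.
#' @return The uppercased sequences.
#' @export
dna <- function(x) {
  if (!is.character(x)) stop("sequence must be a character vector")
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid character in DNA sequence: ",
         substr(gsub("[ACGTN]", "", x[bad][1]), 1, 1))
  }
  x
}

#' Reverse-complement DNA
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorized.
#'
#' @param s Character vector over \{A,C,G,T,N\} (lowercase accepted).
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(s) {
  s <- dna(s)
  if (!length(s)) return(character(0))
  if (length(s) > 50L) {
    # batch path: S4 overhead amortized over many strings
    return(unname(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(s)))))
  }
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Translate an in-frame DNA sequence
#'
#' Standard nuclear genetic code; stop codons render as `*` and translation
#' does not terminate early (the full-length peptide is returned).
#'
#' @param orf DNA sequence whose length is a multiple of 3.
#' @return Single-letter amino-acid string.
#' @export
translate_dna <- function(orf) {
  orf <- dna(orf)
  n <- nchar(orf)
  if (n %% 3L != 0L) stop("ORF length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(orf, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("untranslatable codon (contains N): ",
                      codons[which(is.na(aa))[1]])
  paste(aa, collapse = "")
}

#' GC fraction of a sequence
#'
#' @param s Non-empty DNA sequence (scalar or vector).
#' @return Fraction of G+C bases in `[0, 1]`.
#' @export
gc_fraction <- function(s) {
  s <- dna(s)
  n <- nchar(s)
  if (any(n == 0L)) stop("gc_fraction is undefined for an empty sequence")
  gc <- nchar(gsub("[^GC]", "", s))
  gc / n
}

# ---- FASTA / FASTQ ---------------------------------------------------------

#' Read a FASTA file
#'
#' @param path Path to a (possibly line-wrapped) multi-record FASTA file.
#' @return Named character vector of uppercased sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record '",
         names(seqs)[which(nchar(seqs) == 0L)[1]], "' in ", path)
  }
  dna(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  set <- Biostrings::DNAStringSet(dna(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a 4-line FASTQ file
#'
#' Qualities are retained but most of the pipeline ignores them (edits are
#' called from merged, already-filtered reads).
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ file: ", path)
  idx <- seq(1L, length(lines), by = 4L)
  ids <- lines[idx]
  if (!all(startsWith(ids, "@"))) stop("malformed FASTQ header in ", path)
  data.frame(id = sub("\\s.*$", "", sub("^@", "", ids)),
             seq = dna(lines[idx + 1L]),
             qual = lines[idx + 3L],
             stringsAsFactors = FALSE)
}

#' Write a 4-line FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (default constant Q40, Phred+33 `I`).
#' @param path Output path (a `.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---- Gene targets ----------------------------------------------------------

#' Construct a gene target
#'
#' A `gene_target` is an ORF embedded in genomic context, oriented so the
#' ORF reads 5'->3' on the plus strand of `context`. Callers working from a
#' minus-strand gene must reverse-complement the region first (see
#' [gene_target_from_gff()]). Design near the ORF ends needs at least 73 bp
#' of flank (50-bp homology arm + 20-bp guide + 3-bp PAM); shorter flanks
#' are permitted here but the affected designs are rejected per-slot.
#'
#' @param gene_id Identifier used in cassette ids.
#' @param context DNA sequence containing the ORF plus flanks.
#' @param orf_start 0-based offset of the ORF's first base in `context`.
#' @param orf_length ORF length in bases (multiple of 3).
#' @param check_start Require the annotated start codon to be ATG.
#' @return Object of class `gene_target`.
#' @export
gene_target <- function(gene_id, context, orf_start, orf_length,
                        check_start = TRUE) {
  context <- dna(context)
  stopifnot(length(context) == 1L, orf_start >= 0, orf_length > 0)
  if (orf_length %% 3L != 0L) {
    stop("ORF length ", orf_length, " is not a multiple of 3")
  }
  if (orf_start + orf_length > nchar(context)) {
    stop("ORF extends beyond the supplied context")
  }
  start_codon <- substr(context, orf_start + 1L, orf_start + 3L)
  if (check_start && start_codon != "ATG") {
    stop("context does not encode an ATG start codon at orf_start (found ",
         start_codon, ")")
  }
  structure(list(gene_id = gene_id, context = context,
                 orf_start = as.integer(orf_start),
                 orf_length = as.integer(orf_length)),
            class = "gene_target")
}

#' @export
print.gene_target <- function(x, ...) {
  cat("<gene_target> ", x$gene_id, ": ", x$orf_length / 3L, " codons, ",
      "flanks ", x$orf_start, "/",
      nchar(x$context) - x$orf_start - x$orf_length, " bp\n", sep = "")
  invisible(x)
}

#' Number of codons in a target's ORF
#' @param target A [gene_target()].
#' @return Integer codon count (including the terminal stop if present).
#' @export
n_codons <- function(target) target$orf_length %/% 3L

#' Extract the ORF sequence of a target
#' @param target A [gene_target()].
#' @return The ORF as a character scalar.
#' @export
orf_seq <- function(target) {
  substr(target$context, target$orf_start + 1L,
         target$orf_start + target$orf_length)
}

#' Describe one codon of a gene target
#'
#' @param target A [gene_target()].
#' @param codon_index 1-based codon number (codon 1 = start codon).
#' @return List with `codon_index`, `offset` (0-based position of the
#'   codon's first base in context), `wt_codon` and `wt_aa`.
#' @export
codon_site <- function(target, codon_index) {
  nc <- n_codons(target)
  if (codon_index < 1L || codon_index > nc) {
    stop("codon_index ", codon_index, " outside ORF (1..", nc, ")")
  }
  offset <- target$orf_start + 3L * (codon_index - 1L)
  wt_codon <- substr(target$context, offset + 1L, offset + 3L)
  list(codon_index = as.integer(codon_index), offset = as.integer(offset),
       wt_codon = wt_codon, wt_aa = translate_dna(wt_codon))
}

#' Build a gene target from a genome FASTA and a GFF3 annotation
#'
#' Extracts one CDS interval (single-exon; introns are out of scope) plus
#' symmetric flanks and re-orients minus-strand genes so the returned
#' context carries the ORF on its plus strand.
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param gff Path to a GFF3 file containing a CDS feature for `gene_id`.
#' @param gene_id Value matched against the GFF attributes.
#' @param flank Flank length to include on each side (default 500 bp).
#' @return A [gene_target()].
#' @export
gene_target_from_gff <- function(genome_fasta, gff, gene_id, flank = 500L) {
  genome <- read_fasta(genome_fasta)
  g <- utils::read.table(gff, sep = "\t", quote = "", comment.char = "#",
                         col.names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attr"),
                         stringsAsFactors = FALSE)
  g <- g[g$type == "CDS" & grepl(gene_id, g$attr, fixed = TRUE), ]
  if (nrow(g) == 0L) stop("no CDS feature for '", gene_id, "' in ", gff)
  if (nrow(g) > 1L) stop("multi-exon CDS not supported (", gene_id, ")")
  chrom <- genome[[g$seqid]]
  if (is.null(chrom)) stop("sequence '", g$seqid, "' absent from genome")
  lo <- max(1L, g$start - flank)
  hi <- min(nchar(chrom), g$end + flank)
  region <- substr(chrom, lo, hi)
  if (g$strand == "-") {
    region <- reverse_complement(region)
    orf_start <- hi - g$end
  } else {
    orf_start <- g$start - lo
  }
  gene_target(gene_id, region, orf_start, g$end - g$start + 1L)
}
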
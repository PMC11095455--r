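Package: chase
Title: Design and Quantification of CRISPR Homology-Directed Saturation
    Editing Libraries
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing saturation genome-editing cassette
    libraries in which each oligo fuses a homology-directed-repair donor to
    its 20-bp CRISPR guide. Donors carry the intended codon edit together
    with synonymous substitutions that eliminate the PAM or protospacer so
    the edited locus and the donor itself are not re-cut. Candidate designs
    are filtered (polyT runs), ranked (PAM-codon distance, seed purine
    content, guide GC range, 12-bp seed off-target counts against a genome
    k-mer index) and the top cassettes per codon swap are exported as an
    oligo pool with a design-landscape report. A companion amplicon-NGS
    quantifier calls designed edits in merged reads, normalizes counts per
    million, and summarizes per-codon saturation. A read/gene simulator
    makes the whole design-to-quantification loop testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
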
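---
title: "Saturation editing cassette design: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation editing cassette design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chase)
```

## The editing model

A saturation editing library replaces each codon of an ORF, in its
chromosomal context, with the codons for all 20 amino acids (including a
synonymous recoding of the wild-type amino acid) plus a stop codon — 21
target classes per codon. Every library member is a single synthesized
oligo fusing an HDR donor (5') to its 20-bp guide (3'): the donor-guide
linkage means a sequenced donor identifies the guide that produced it.

The donor must not be re-cut after (or before) recombination. We model
cleavability as a hard predicate: a locus is cleavable if and only if the
20-mer at the guide's position exactly matches the wild-type protospacer
*and* the adjacent triplet still matches the design PAM pattern. This is
deliberately conservative — single distal mismatches can in reality still
be cut, which is why elimination prefers PAM-destroying and seed-proximal
substitutions (below). Any codon edit overlapping the protospacer already
falsifies the predicate; the search for additional synonymous
substitutions then returns the empty set.

### Synonymous elimination search

When the codon edit leaves the locus cleavable, additional synonymous
substitutions are searched in a fixed preference order:

1. **PAM kill** — a synonymous recoding of a codon overlapping the PAM
   that makes the triplet fail its pattern (for `NGN`, the middle G; for
   `NGG`, either G);
2. **seed kill** — one synonymous mismatch inside the PAM-proximal 4-bp
   seed;
3. **proximal kill** — at least two synonymous mismatches inside the
   PAM-proximal 10 bp (one or two codon recodings combined).

Within each tier candidates are ordered by substitution count, then
proximity to the PAM, then alphabetically by the substituted base, making
the search deterministic. A candidate is rejected if it would create a new
`TTTTT` run or a new perfect protospacer match inside the donor (the donor
must not become self-targeting). If no tier yields a valid candidate the
cassette is infeasible and is recorded as a missing design — this is what
happens, for example, when the protospacer is covered by Met/Trp codons,
which admit no synonymous change.

Substitutions are only placed inside the ORF (synonymity is undefined in
flanks); guides and PAMs may extend into the flanks provided the codon
edit itself suffices or the needed substitutions fall inside the ORF.

## Ranking and selection

Candidates surviving the polyT filter are sorted lexicographically by:

| key | direction | rationale |
|-----|-----------|-----------|
| 12-bp-seed off-target count | ascending | a guide cutting elsewhere is worst |
| PAM-codon distance (bp) | ascending | shorter conversion tracts recombine better |
| seed purine (A+G) fraction | descending | purine-rich seeds correlate with activity |
| guide GC in 30–80% | in-range first | extreme GC guides are less active |
| (PAM offset, strand) | — | deterministic tie-break |

No canonical priority exists for these features in the literature they
come from; the order above is this package's documented choice
(off-targets first), and the report records it so alternative orderings
can be evaluated. GC
range is a rank key by default and a hard filter under `strict_gc`; both
30% and 80% are inclusive, since the range is quoted without open/closed
qualification. The polyT scan covers donor + guide (the transcribed
cassette) but not the assembly adapters, because the filtered failure mode
is premature termination of the expressed cassette.

Up to `k = 4` cassettes are kept per codon swap. Two further rules matter:

* **distance metric** — the number of bases strictly between the codon and
  the PAM triplet (0 when they overlap or abut), symmetric and
  strand-agnostic; whether the original pipeline measured PAM-to-codon or
  cut-site-to-codon is not stated, so this is a fixed documented choice.
* **unique variants** — two candidates with identical substitution sets
  produce the same edited allele and are indistinguishable in sequencing;
  selection keeps only the best-ranked cassette per substitution set,
  library-wide. This keeps the cassette count equal to the unique-variant
  count and makes perfect-call assignment unambiguous.

## Codon choices

Replacement codons default to the most frequent *S. cerevisiae* codon per
amino acid (Kazusa usage table); the synonymous design uses the
highest-usage codon different from the wild-type codon, and the stop
design uses `TAA` (the most used yeast stop). Nothing biological forces
these picks — they are explicit defaults, overridable through
`codon_table()`. Met and Trp have no synonymous
design; those slots are reported missing with reason `no_codon_change`.

## Off-target counting

`build_seed_index()` indexes, on both strands of a genome, every 12-mer
that sits immediately 5' of a pattern-matching PAM. `count_offtargets()`
is exact-match lookup of a guide's PAM-proximal 12-mer minus the on-target
occurrence; requiring an adjacent PAM restricts hits to cleavable sites.
`find_seed_matches()` provides the looser BLAST-like survey mode (no PAM,
contiguous PAM-proximal match of at least 10 bp). When no genome is
supplied, off-target counts are 0 for all candidates and ranking falls
through to distance.

## Quantification model

Reads are merged amplicons. A read is retained only if it carries the
forward primer as a prefix, the reverse-complemented reverse primer as a
suffix, and has exactly the reference length — a substitution-only model.
InDel-carrying reads are dropped as `filtered_length`; consequently
deletion cassettes from custom mode are not quantifiable by this module.
Calling compares the read position-wise with the wild-type segment:

* empty mismatch set → `wild_type`;
* set equal to one cassette's designed set (restricted to the segment) →
  `perfect`, assigned to that cassette;
* non-empty subset of some cassette's set → `imperfect` (partial HDR,
  e.g. codon mutations without the PAM kill);
* any mismatch at a position/base no cassette designs → `unmatched`.

The `unmatched` rule is stricter than requiring consistency only at
designed positions; it cleanly separates sequencing noise from partial
HDR, at the cost of discarding reads with one stray error on an otherwise
perfect allele (at amplicon error rates this is a small, unbiased loss).
Normalization is `raw x 1,000,000 / total retained reads per segment`, so
normalized counts sum to 1,000,000 across statuses; a segment with zero
retained reads is flagged rather than divided by zero. A cassette whose
substitutions span two segments is counted per segment against the
restricted sets; cross-segment joint calls are not attempted (reads are
independent after merging).

## What the simulator does and does not emulate

`make_toy_gene()` builds a random context with an in-frame ORF (ATG start,
no internal stop, TAA end) and verbatim planted features (PAM deserts,
duplicated seeds, polyT traps) at recorded offsets. `simulate_reads()`
applies a genotype's substitutions to its segment reference, injects
uniform per-base substitution errors, and flips half the reads. Abundances
are exact counts by default so round-trip tests are exact; a multinomial
mode exists for statistical tests.

Not emulated: InDels (by design, matching the quantifier's read model),
position- and motif-dependent Illumina error profiles, PCR amplification
bias, chimeric reads. A green round-trip test therefore establishes the
correctness of the design/counting logic, not robustness to those
artifacts.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; codon numbers are 1-based.
* Normalized-count comparisons use tolerance 1e-9 (pure floating-point
  noise); all other checks are exact integer/string equality.
* The default codon range excludes the start codon and a terminal stop
  codon; missing-slot accounting is per (codon, class, rank-slot), so
  `cassettes + missing = codons x 21 x k`.
* An empty candidate set is a recorded missing design, never an error;
  per-slot failures never abort a library run.
* Genome-absent designs treat every off-target count as 0; genome-present
  designs with a declared context location raise a consistency error if
  the on-target seed is not found in the index.

## Known limitations

* Published library sizes for ADE2/SPT15 depend on the S288C assembly and
  on designer-side choices (codon picks, key priority, distance metric)
  that are not pinned down by the published counts alone; this package
  reproduces the procedure and emits per-slot detail for diagnosis, but
  exact-count concordance cannot be asserted without the genome and the
  original design tables.
* The cleavability predicate is binary; no mismatch-tolerant off-target
  scoring (CFD/MIT) is attempted.
* Multi-exon genes and edits spanning introns are out of scope; the GFF
  front-end accepts single-CDS features only.
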
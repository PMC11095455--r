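test_that("enumerate_pams finds pattern matches on both strands", {
  ctx <- "AAAAGGAAAA"
  ngg <- enumerate_pams(ctx, "NGG")
  expect_equal(nrow(ngg), 1L)
  expect_equal(ngg$offset, 3L)
  expect_equal(ngg$strand, "+")
  expect_equal(ngg$pam_seq, "AGG")

  ngn <- enumerate_pams(ctx, "NGN")
  expect_equal(ngn$offset, c(3L, 4L))
  expect_equal(ngn$strand, c("+", "+"))

  expect_equal(nrow(enumerate_pams(ctx, "NGG", window = c(0, 0))), 0L)
  expect_error(enumerate_pams(ctx, "NGG", window = c(0, 99)), "bounds")
})

test_that("enumerate_pams agrees with a brute-force scan", {
  set.seed(21)
  for (pattern in c("NGG", "NGN", "NRN")) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    got <- enumerate_pams(ctx, pattern)
    exp <- oracle_scan_pams(ctx, pattern)
    exp <- exp[order(exp$offset, exp$strand == "-"), ]
    expect_equal(got$offset, exp$offset)
    expect_equal(got$strand, exp$strand)
    expect_equal(got$pam_seq, exp$pam_seq)
  }
})

test_that("guides reconstruct a contiguous 23-base window", {
  tg <- make_toy_gene(orf_codons = 12, seed = 2)
  pams <- enumerate_pams(tg$context, "NGN", require_protospacer_fit = TRUE)
  for (r in sample(nrow(pams), 10)) {
    p <- pams[r, ]
    g <- guide_for_pam(tg$context, p$offset, p$strand)
    expect_equal(nchar(g$protospacer), 20L)
    expect_equal(g$seed4, substr(g$protospacer, 17, 20))
    expect_equal(g$seed12, substr(g$protospacer, 9, 20))
    window23 <- paste0(g$protospacer, p$pam_seq)
    plus23 <- if (p$strand == "+") {
      substr(tg$context, p$offset - 20 + 1, p$offset + 3)
    } else {
      reverse_complement(substr(tg$context, p$offset + 1, p$offset + 23))
    }
    expect_equal(window23, plus23)
  }
})

test_that("PAM-codon distance is an interval gap, zero on overlap/abutment", {
  expect_equal(pam_codon_distance(10L, 10L), 0L)   # identical interval
  expect_equal(pam_codon_distance(8L, 10L), 0L)    # overlap
  expect_equal(pam_codon_distance(7L, 10L), 0L)    # abut (pam ends at 10)
  expect_equal(pam_codon_distance(6L, 10L), 1L)
  expect_equal(pam_codon_distance(13L, 10L), 0L)   # abut on the right
  expect_equal(pam_codon_distance(14L, 10L), 1L)
  expect_equal(pam_codon_distance(34L, 10L), 21L)  # just outside the window
})

test_that("candidate_pams_for_codon equals a brute-force distance filter", {
  tg <- make_toy_gene(orf_codons = 20, seed = 9)
  for (idx in c(2L, 7L, 19L)) {
    site <- codon_site(tg, idx)
    got <- candidate_pams_for_codon(tg, site, "NGN", max_distance = 20L)
    all_pams <- oracle_scan_pams(tg$context, "NGN")
    keep <- logical(nrow(all_pams))
    L <- nchar(tg$context)
    for (r in seq_len(nrow(all_pams))) {
      p <- all_pams$offset[r]
      gap <- max(site$offset - (p + 3), p - (site$offset + 3), 0)
      fits <- if (all_pams$strand[r] == "+") p - 20 >= 0 else p + 23 <= L
      keep[r] <- gap <= 20 && fits
    }
    exp <- all_pams[keep, ]
    exp <- exp[order(exp$offset, exp$strand == "-"), ]
    expect_equal(got$offset, exp$offset)
    expect_equal(got$strand, exp$strand)
    expect_true(all(got$distance <= 20))
  }
})

test_that("plan_codon_edit emits one substitution per differing base", {
  tg <- gene_target("g", paste0(strrep("C", 75), "ATGACTAAATAA",
                                strrep("C", 75)), 75, 12)
  site <- codon_site(tg, 2)
  expect_equal(site$wt_codon, "ACT")

  full <- plan_codon_edit(site, "TTC")  # Thr ACT -> Phe TTC
  expect_equal(nrow(full), 3L)
  expect_equal(full$offset, site$offset + 0:2)
  expect_equal(full$alt, c("T", "T", "C"))
  expect_true(all(full$purpose == "codon_edit"))

  one <- plan_codon_edit(site, "ACC")
  expect_equal(nrow(one), 1L)
  expect_equal(one$offset, site$offset + 2L)

  expect_error(plan_codon_edit(site, "ACT"), "no-op")
})

# Layout helper: flank + ATG + ACT + filler codons + TAA + flank, with the
# filler chosen by the caller so PAM/protospacer content is controlled.
synthetic_target <- function(filler, flank = 80L) {
  orf <- paste0("ATG", "ACT", paste(filler, collapse = ""), "TAA")
  gene_target("syn", paste0(strrep("C", flank), orf, strrep("A", flank)),
              flank, nchar(orf))
}

test_that("eliminate_recutting: codon edit destroying the PAM suffices", {
  # PAM inside the target codon itself: the AGG codon is the NGG PAM
  tg <- gene_target("g", paste0(strrep("C", 80), "ATGAGGAAAAAGAAATAA",
                                strrep("A", 80)), 80, 18)
  site <- codon_site(tg, 2)
  pam <- list(offset = site$offset, strand = "+", pam_seq = "AGG",
              pattern = "NGG")
  guide <- guide_for_pam(tg$context, pam$offset, pam$strand)
  edit <- plan_codon_edit(site, "TTC")
  kill <- eliminate_recutting(tg, pam, guide, edit)
  expect_equal(nrow(kill), 0L)
  expect_false(is_cleavable(apply_substitutions(tg$context, edit), pam,
                            guide))
})

test_that("eliminate_recutting kills an out-of-codon PAM synonymously", {
  # codon 10 = AGG (Arg) carries the NGG PAM; the ACT->TTC edit at codon 2
  # is outside the protospacer, so a synonymous AGG->AGA pam_kill is needed
  filler <- c("GAA", "GAT", "GCT", "GAA", "GAT", "GCT", "GAA", "AGG")
  tg <- synthetic_target(filler)
  site <- codon_site(tg, 2)
  pam_off <- codon_site(tg, 10)$offset
  pam <- list(offset = pam_off, strand = "+", pam_seq = "AGG",
              pattern = "NGG")
  guide <- guide_for_pam(tg$context, pam_off, "+")
  edit <- plan_codon_edit(site, "TTC")
  expect_true(is_cleavable(apply_substitutions(tg$context, edit), pam, guide))

  kill <- eliminate_recutting(tg, pam, guide, edit)
  expect_equal(nrow(kill), 1L)
  expect_equal(kill$purpose, "pam_kill")
  expect_equal(kill$offset, pam_off + 2L)  # AGG -> AGA, third base
  expect_equal(kill$alt, "A")
  edited <- apply_substitutions(tg$context, rbind(edit, kill))
  expect_false(is_cleavable(edited, pam, guide))
  # synonymity: translation unchanged except the target codon
  aa_ed <- translate_dna(substr(edited, tg$orf_start + 1,
                                tg$orf_start + tg$orf_length))
  aa_wt <- translate_dna(orf_seq(tg))
  diff <- which(strsplit(aa_ed, "")[[1]] != strsplit(aa_wt, "")[[1]])
  expect_equal(diff, 2L)
})

test_that("eliminate_recutting is infeasible across Met/Trp-only context", {
  # protospacer and PAM covered entirely by ATG/TGG codons: no synonymous
  # substitution exists anywhere in PAM, seed or proximal 10 bases
  filler <- c("ATG", "ATG", "TGG", "ATG", "TGG", "ATG", "ATG", "TGG")
  tg <- synthetic_target(filler)
  site <- codon_site(tg, 2)
  pam_off <- codon_site(tg, 10)$offset  # codon 10 = TGG matches NGG
  pam <- list(offset = pam_off, strand = "+", pam_seq = "TGG",
              pattern = "NGG")
  guide <- guide_for_pam(tg$context, pam_off, "+")
  edit <- plan_codon_edit(site, "TTC")
  expect_true(is_cleavable(apply_substitutions(tg$context, edit), pam, guide))
  expect_null(eliminate_recutting(tg, pam, guide, edit))
})

test_that("build_donor span arithmetic, orientation and reversibility", {
  tg <- make_toy_gene(orf_codons = 20, seed = 14)
  site <- codon_site(tg, 8)
  one <- data.frame(offset = site$offset, ref = substr(site$wt_codon, 1, 1),
                    alt = setdiff(c("A", "C", "G", "T"),
                                  substr(site$wt_codon, 1, 1))[1],
                    purpose = "codon_edit")
  d1 <- build_donor(tg, one)
  expect_equal(nchar(d1$emitted_seq), 101L)  # 50 + 1 + 50

  edit <- plan_codon_edit(site, synonymous_codons(codon_table(),
                                                  site$wt_codon)[1])
  far <- data.frame(offset = site$offset + 8L,
                    ref = substr(tg$context, site$offset + 9,
                                 site$offset + 9),
                    alt = setdiff(c("A", "C", "G", "T"),
                                  substr(tg$context, site$offset + 9,
                                         site$offset + 9))[1],
                    purpose = "pam_kill")
  full <- rbind(data.frame(offset = site$offset + 0:2,
                           ref = strsplit(site$wt_codon, "")[[1]],
                           alt = strsplit("TTC", "")[[1]],
                           purpose = "codon_edit"), far)
  full <- full[full$ref != full$alt, ]
  d2 <- build_donor(tg, full)
  expect_equal(nchar(d2$emitted_seq), 109L)  # 50 + 9 + 50
  expect_equal(d2$emitted_seq,
               paste0(d2$left_arm, d2$core, d2$right_arm))

  # minus-strand rule: emitted is the reverse complement of the window
  d2m <- build_donor(tg, full, strand = "-")
  expect_equal(d2m$emitted_seq, reverse_complement(d2$emitted_seq))

  # reversibility: reverting substitutions reproduces wild-type context
  win_wt <- substr(tg$context, d2$start + 1, d2$end)
  reverted <- d2$emitted_seq
  for (i in seq_len(nrow(full))) {
    pos <- full$offset[i] - d2$start + 1L
    substr(reverted, pos, pos) <- full$ref[i]
  }
  expect_equal(reverted, win_wt)

  # arm integrity: 50 terminal bases are substitution-free context
  expect_equal(d2$left_arm, substr(tg$context, d2$start + 1, d2$start + 50))
  expect_equal(d2$right_arm, substr(tg$context, d2$end - 49, d2$end))

  expect_error(build_donor(tg, data.frame(offset = 3L, ref =
    substr(tg$context, 4, 4), alt = "A", purpose = "x")), "flank")
})

test_that("assemble_cassette appends guide then adapters", {
  tg <- make_toy_gene(orf_codons = 15, seed = 6)
  site <- codon_site(tg, 5)
  subs <- plan_codon_edit(site, design_codon_for_class(codon_table(),
                                                       site$wt_codon, "*"))
  donor <- build_donor(tg, subs)
  proto <- strrep("AC", 10)
  asm <- assemble_cassette(donor, proto)
  expect_equal(nchar(asm$oligo), nchar(donor$emitted_seq) + 20L)
  expect_true(endsWith(asm$core, proto))
  asm2 <- assemble_cassette(donor, proto, adapters = c("GGG", "CCC"))
  expect_equal(asm2$oligo, paste0("GGG", asm$core, "CCC"))
  # polyT created at the donor-guide junction is caught by the filter
  junction <- assemble_cassette(donor, paste0("TT", strrep("AC", 9)))
  if (endsWith(donor$emitted_seq, "TTT")) expect_true(has_polyT(junction$core))
  expect_true(has_polyT(paste0(substr(donor$emitted_seq, 1, 80), "TTT",
                               "TT", strrep("AC", 9))))
})
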
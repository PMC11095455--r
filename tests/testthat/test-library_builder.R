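test_that("stop-scan per-codon counts match a brute-force slot oracle", {
  tg <- make_toy_gene(orf_codons = 10, seed = 17)
  spec <- design_spec(pam_pattern = "NGN", k = 4, mode = "stop_scan")
  lib <- design_stop_library(tg, spec)
  man <- library_manifest(lib)
  ct <- codon_table()
  for (idx in 2:(n_codons(tg) - 1)) {
    site <- codon_site(tg, idx)
    new_codon <- design_codon_for_class(ct, site$wt_codon, "*")
    # oracle: enumerate PAMs by direct scan, run the per-candidate design
    # operations, count distinct feasible variants surviving polyT
    pams <- oracle_scan_pams(tg$context, "NGN")
    variants <- character(0)
    for (r in seq_len(nrow(pams))) {
      p <- pams$offset[r]; s <- pams$strand[r]
      gap <- max(site$offset - (p + 3), p - (site$offset + 3), 0)
      if (gap > 20) next
      g <- guide_for_pam(tg$context, p, s)
      if (is.null(g)) next
      edit <- plan_codon_edit(site, new_codon)
      pam <- list(offset = p, strand = s, pam_seq = pams$pam_seq[r],
                  pattern = "NGN")
      kill <- eliminate_recutting(tg, pam, g, edit)
      if (is.null(kill)) next
      subs <- rbind(edit, kill)
      donor <- tryCatch(build_donor(tg, subs, strand = s),
                        error = function(e) NULL)
      if (is.null(donor)) next
      if (has_polyT(paste0(donor$emitted_seq, g$protospacer))) next
      variants <- union(variants, paste(sort(paste0(subs$offset, subs$alt)),
                                        collapse = ","))
    }
    got <- sum(man$codon_index == idx)
    expect_equal(got, min(4L, length(variants)),
                 info = paste("codon", idx))
  }
  # slot accounting: cassettes + missing = codons x classes x k per slot
  rep <- lib$report
  expect_equal(rep$total_cassettes + rep$missing_slots, rep$total_slots)
  expect_equal(rep$total_slots, length(rep$codons) * 1L * 4L)
})

test_that("saturation mode: slot accounting, categories, invariants", {
  tg <- make_toy_gene(orf_codons = 12, seed = 23)
  lib <- design_saturation_library(tg, design_spec(k = 2))
  rep <- lib$report
  expect_equal(rep$total_cassettes + rep$missing_slots, rep$total_slots)
  expect_equal(rep$total_slots, length(rep$codons) * 21L * 2L)
  man <- library_manifest(lib)
  expect_false(any(duplicated(man$id)))
  # category consistency with translation
  for (cs in lib$cassettes) {
    wt_aa <- translate_dna(cs$wt_codon); new_aa <- translate_dna(cs$new_codon)
    expected <- if (new_aa == "*") "stop"
      else if (new_aa == wt_aa) "synonymous" else "missense"
    expect_equal(cs$category, expected)
    # re-cut prevention and arm integrity
    edited <- apply_substitutions(tg$context, cs$substitutions)
    expect_false(is_cleavable(edited, cs$pam, cs$guide))
    expect_false(has_polyT(cs$core))
    expect_equal(cs$donor$left_arm,
                 substr(tg$context, cs$donor$start + 1, cs$donor$start + 50))
  }
  # library-wide unique variants
  keys <- vapply(lib$cassettes, cassette_variant_key, character(1))
  expect_false(any(duplicated(keys)))
})

test_that("design output is deterministic", {
  tg <- make_toy_gene(orf_codons = 10, seed = 29)
  spec <- design_spec(k = 3)
  m1 <- library_manifest(design_saturation_library(tg, spec))
  m2 <- library_manifest(design_saturation_library(tg, spec))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  utils::write.table(m1, f1, sep = "\t"); utils::write.table(m2, f2, sep = "\t")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a planted PAM desert yields no_pam_in_window missing slots", {
  desert <- strrep("ATTATA", 10)  # 60 bp, A/T only: no NGN on either strand
  tg <- make_toy_gene(orf_codons = 40, seed = 35, flank = 80,
                      planted = list(list(offset = 80L + 30L, seq = desert)))
  expect_equal(nrow(enumerate_pams(desert, "NGN")), 0L)
  lib <- design_stop_library(tg, design_spec(pam_pattern = "NGN", k = 4,
                                             mode = "stop_scan"))
  # codons fully inside the desert, further than 20 bp from its edges
  inner_first <- (30 + 23) %/% 3 + 2   # conservative inner range
  inner_last <- (30 + 60 - 23) %/% 3
  inner <- seq(inner_first, inner_last)
  missing <- lib$report$missing
  expect_true(all(inner %in% missing$codon_index))
  expect_true(all(missing$reason[missing$codon_index %in% inner] ==
                    "no_pam_in_window"))
})

test_that("landscape: all-A context gives an all-zero matrix; NGN >= NGG", {
  allA <- gene_target("flat", strrep("A", 400), 100, 60, check_start = FALSE)
  ls <- landscape_matrix(allA, design_spec(pam_pattern = "NGN"))
  expect_true(all(ls$matrix == 0))
  expect_equal(ls$pct_codons_uneditable, 100)

  for (seed in c(3, 13)) {
    tg <- make_toy_gene(orf_codons = 10, seed = seed)
    ngn <- landscape_matrix(tg, design_spec(pam_pattern = "NGN"))
    ngg <- landscape_matrix(tg, design_spec(pam_pattern = "NGG"))
    expect_true(all(ngn$matrix >= ngg$matrix))
  }
})

test_that("export/import round trip and donor reconstruction", {
  tg <- make_toy_gene(orf_codons = 10, seed = 41)
  lib <- design_stop_library(tg, design_spec(k = 2, mode = "stop_scan"))
  prefix <- file.path(withr::local_tempdir(), "lib")
  paths <- export_library(lib, prefix)
  expect_true(all(file.exists(paths)))

  man <- library_manifest(lib)
  fasta <- read_fasta(paths[["fasta"]])
  expect_equal(length(fasta), nrow(man))
  expect_equal(unname(fasta), man$oligo)

  back <- read_library_manifest(paths[["manifest"]])
  expect_equal(back, man)

  # substitution column re-applied to wild-type context reproduces donors
  for (i in seq_len(nrow(back))) {
    subs <- chase:::parse_substitutions(back$substitutions[i])
    edited <- apply_substitutions(tg$context, subs)
    lo <- min(subs$offset) - 50L
    hi <- max(subs$offset) + 51L
    win <- substr(edited, lo + 1, hi)
    if (back$strand[i] == "-") win <- reverse_complement(win)
    expect_equal(win, back$donor[i])
  }
})

test_that("custom mode: deletion donors and codon swaps", {
  tg <- make_toy_gene(orf_codons = 20, seed = 47)
  # 8-bp deletion inside the ORF, spanning a codon boundary
  del_start <- tg$orf_start + 10L
  edits <- list(list(type = "deletion", start = del_start,
                     end = del_start + 8L))
  lib <- design_custom(tg, edits, design_spec(k = 2, mode = "custom"))
  expect_gt(length(lib$cassettes), 0L)
  for (cs in lib$cassettes) {
    expect_equal(nchar(cs$donor$emitted_seq), 100L)  # 50 + 0 + 50
    expect_equal(cs$category, "deletion")
    # deletion overlaps the protospacer/PAM site (re-cut prevention)
    lo <- min(cs$guide$proto_start, cs$pam$offset)
    hi <- max(cs$guide$proto_start + 20L, cs$pam$offset + 3L)
    expect_true(lo < del_start + 8L && hi > del_start)
  }

  # a single codon-swap edit reproduces the saturation slot for that codon
  site <- codon_site(tg, 6)
  ct <- codon_table()
  new_codon <- design_codon_for_class(ct, site$wt_codon, "*")
  custom <- design_custom(tg, list(list(type = "codon", codon_index = 6,
                                        new_codon = new_codon)),
                          design_spec(k = 4, mode = "custom"))
  stop_lib <- design_stop_library(tg, design_spec(k = 4, mode = "stop_scan"))
  stop6 <- Filter(function(x) x$codon_index == 6, stop_lib$cassettes)
  expect_equal(vapply(custom$cassettes, cassette_variant_key, character(1)),
               vapply(stop6, cassette_variant_key, character(1)))
})
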
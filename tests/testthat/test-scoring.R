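test_that("frequencies normalize to one", {
  expect_equal(frequencies(counts_from(c(AY = 5L, BY = 15L)))[["AY"]], 0.25)
  expect_equal(frequencies(counts_from(c(AY = 7L)))[["AY"]], 1.0)
  set.seed(41)
  big <- counts_from(setNames(sample(1:50, 200, replace = TRUE),
                              distinct_peptides(200, 4)))
  expect_equal(sum(frequencies(big)), 1, tolerance = 1e-9)
  expect_error(frequencies(count_peptides(make_records(character(0)))),
               "empty")
})

test_that("per-peptide enrichment is the sorted/unsorted frequency ratio", {
  t1 <- counts_from(c(AAAY = 10L, CCCY = 30L), "s", TRUE)
  t2 <- counts_from(c(AAAY = 10L, CCCY = 30L), "u", FALSE)
  et <- enrichment_scores(t1, t2)
  expect_true(all(et$enrichment == 1))
  expect_true(all(et$log2_enrichment == 0))

  # freq_sorted 0.30 vs freq_unsorted 0.10 -> 3.0
  ts <- counts_from(c(AAAY = 30L, CCCY = 70L), "s", TRUE)
  tu <- counts_from(c(AAAY = 10L, CCCY = 90L), "u", FALSE)
  et2 <- enrichment_scores(ts, tu)
  expect_equal(et2$enrichment[et2$peptide == "AAAY"], 3.0)

  # zero unsorted frequency with pseudocount 0 is flagged, not infinite
  ts3 <- counts_from(c(AAAY = 5L, GGGY = 5L), "s", TRUE)
  tu3 <- counts_from(c(AAAY = 10L), "u", FALSE)
  et3 <- enrichment_scores(ts3, tu3)
  row <- et3[et3$peptide == "GGGY", ]
  expect_true(row$undefined)
  expect_true(is.na(row$enrichment))
  et3p <- enrichment_scores(ts3, tu3, pseudocount = 0.5)
  expect_true(all(is.finite(et3p$enrichment)))
})

test_that("enrichment matches an independent arithmetic recomputation to 1e-12", {
  set.seed(42)
  peps <- distinct_peptides(100, 6)
  cs <- setNames(sample(0:200, 100, replace = TRUE), peps)
  cu <- setNames(sample(1:200, 100, replace = TRUE), peps)
  cs[1] <- 1L  # keep every peptide present in at least one sample
  ts <- counts_from(cs[cs > 0], "s", TRUE)
  tu <- counts_from(cu, "u", FALSE)
  et <- enrichment_scores(ts, tu)
  # direct recomputation, no package code
  for (p in et$peptide) {
    fs <- unname(ifelse(p %in% names(cs), cs[p], 0)) / sum(cs)
    fu <- unname(cu[p]) / sum(cu)
    want <- fs / fu
    got <- et$enrichment[et$peptide == p]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("position enrichment divides per-column frequencies and masks the center", {
  peps <- c("AYA", "CYC", "AYC")
  ms <- position_residue_counts(peps, 3, center = 2)
  pe_id <- position_enrichment(ms, ms)
  off <- pe_id$ratio[, -2]
  expect_true(all(is.na(off) | off == 1))
  expect_true(all(is.na(pe_id$ratio[, 2])))   # masked central column

  # {D:50, E:50} vs {D:75, E:25} -> 1.5 and 0.5
  mu <- position_residue_counts(c(rep("D", 50), rep("E", 50)), 1)
  msrt <- position_residue_counts(c(rep("D", 75), rep("E", 25)), 1)
  pe <- position_enrichment(msrt, mu)
  expect_equal(unname(pe$ratio["D", 1]), 1.5)
  expect_equal(unname(pe$ratio["E", 1]), 0.5)
  expect_equal(unname(pe$log2["E", 1]), -1)

  expect_error(position_enrichment(ms, position_residue_counts(peps, 3)),
               "shape|filter")
})

test_that("scanning enrichment is normalized so the reference scores zero", {
  ct <- counts_from(c(AY = 100L, CY = 10L, AD = 5L), "s", TRUE)
  scm <- scanning_matrix_counts(ct, "AY")
  se_id <- scanning_enrichment(scm, scm)
  expect_true(all(se_id$log10 == 0 | is.na(se_id$log10)))

  ct_u <- counts_from(c(AY = 100L, CY = 40L, AD = 20L), "u", FALSE)
  se <- scanning_enrichment(scanning_matrix_counts(ct, "AY"),
                            scanning_matrix_counts(ct_u, "AY"))
  expect_equal(unname(se$log10["A", 1]), 0)
  expect_equal(unname(se$log10["Y", 2]), 0)
  # the depleted mutants score negative
  expect_lt(se$log10["C", 1], 0)
  expect_lt(se$log10["D", 2], 0)
  # hand recomputation of the C mutant cell
  tot_s <- (100 + 10 + 5 + 100) - 100  # raw sum - wt * (L-1), L = 2
  tot_u <- (100 + 40 + 20 + 100) - 100
  want <- log10((10 / tot_s) / (40 / tot_u)) -
    log10((100 / tot_s) / (100 / tot_u))
  expect_equal(unname(se$log10["C", 1]), want, tolerance = 1e-12)
})

test_that("enrichment ratios are invariant to sample-depth scaling", {
  set.seed(51)
  peps <- distinct_peptides(40, 5)
  cs <- setNames(sample(1:100, 40), peps)
  cu <- setNames(sample(1:100, 40), peps)
  e1 <- enrichment_scores(counts_from(cs, "s", TRUE), counts_from(cu, "u"))
  e2 <- enrichment_scores(counts_from(cs * 7L, "s", TRUE), counts_from(cu, "u"))
  expect_equal(e1$enrichment, e2$enrichment, tolerance = 1e-12)

  ms <- position_residue_counts(rep(peps, cs), 5)
  mu <- position_residue_counts(rep(peps, cu), 5)
  ms7 <- ms; ms7$counts <- ms$counts * 7L
  p1 <- position_enrichment(ms, mu)
  p2 <- position_enrichment(ms7, mu)
  expect_equal(p1$ratio, p2$ratio, tolerance = 1e-12)
})

test_that("amber position enrichment compares one-amber subsets", {
  d <- library_design("degenerate", peptide_length = 3L)
  sorted <- c("*YA", "*YA", "AYC", "**A")
  unsorted <- c("*YA", "AY*", "AYC")
  pe <- amber_position_enrichment(sorted, unsorted, d)
  expect_identical(pe$filter_mode, "onestop")
  # identical one-amber subsets give unit ratios
  same <- amber_position_enrichment(c("*YA", "AY*"), c("*YA", "AY*"), d)
  off <- same$ratio[, -2]
  expect_true(all(is.na(off) | off == 1))
  # no amber reads anywhere is an error
  expect_error(amber_position_enrichment(c("AYA"), c("AYC"), d), "one-amber")
})

test_that("logo selection splits single-tyrosine peptides at the cutoff", {
  ts <- counts_from(c(AAAYA = 40L, AYAYA = 30L, CCYCC = 10L, GGGGG = 20L),
                    "s", TRUE)
  tu <- counts_from(c(AAAYA = 10L, AYAYA = 5L, CCYCC = 40L, GGGGG = 45L),
                    "u", FALSE)
  et <- enrichment_scores(ts, tu)
  sel <- select_for_logo(et, cutoff = 3)
  # AYAYA has two tyrosines: excluded from both sets despite high enrichment
  expect_identical(sel$foreground, "AAAYA")
  expect_setequal(sel$background, c("AAAYA", "CCYCC"))
  expect_equal(dim(sel$foreground_pfm), c(21L, 5L))
  expect_equal(colSums(sel$background_pfm), rep(1, 5), ignore_attr = TRUE)

  # nothing above the cutoff -> empty foreground with a warning
  expect_warning(none <- select_for_logo(et, cutoff = 100), "empty")
  expect_length(none$foreground, 0L)

  # cutoff below every defined score -> foreground equals scored background
  sel0 <- select_for_logo(et, cutoff = 1e-9)
  expect_setequal(sel0$foreground, sel0$background)
})

test_that("replicate averaging takes the cell-wise mean of log scores", {
  mu <- position_residue_counts(c(rep("D", 50), rep("E", 50)), 1)
  m1 <- position_residue_counts(c(rep("D", 75), rep("E", 25)), 1)
  m2 <- position_residue_counts(c(rep("D", 50), rep("E", 50)), 1)
  p1 <- position_enrichment(m1, mu)
  p2 <- position_enrichment(m2, mu)
  avg <- average_replicates(list(p1, p2), log_base = 2)
  expect_equal(unname(avg["D", 1]), mean(c(log2(1.5), 0)))
})
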
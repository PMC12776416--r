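test_that("phosphorylation probability follows the reaction-extent closed form", {
  m <- specificity_model(peptide_length = 3L, baseline_rate = 1,
                         exposure_time = 1)
  expect_equal(phosphorylation_probability("AYA", m), 1 - exp(-1))
  expect_equal(phosphorylation_probability("AYA", m, exposure_time = 0), 0)

  # one occupied cell with weight log(4) over a p = 0.1 baseline:
  # p = 1 - 0.9^4
  rate <- -log(0.9)
  m2 <- specificity_model(peptide_length = 3L, baseline_rate = rate,
                          exposure_time = 1)
  m2$weights["C", 1] <- log(4)
  expect_equal(phosphorylation_probability("CYA", m2), 1 - 0.9^4,
               tolerance = 1e-12)
  # monotone in the weight
  m3 <- m2; m3$weights["C", 1] <- log(5)
  expect_gt(phosphorylation_probability("CYA", m3),
            phosphorylation_probability("CYA", m2))

  expect_error(phosphorylation_probability("AY", m), "length")
})

test_that("exposure calibration hits the target extent and is monotone", {
  d <- x5yx5_design()
  cfg <- simulation_config(d, n_cells = 5000, seed = 61L)
  pop <- sample_library(cfg)
  model <- random_specificity_model(d, sd = 0.5, seed = 62L)

  t_mid <- calibrate_exposure(model, pop, 0.375)
  p <- phosphorylation_probability(names(pop), model, exposure_time = t_mid)
  extent <- sum(p * pop) / sum(pop)
  expect_gte(extent, 0.37)
  expect_lte(extent, 0.38)

  t_lo <- calibrate_exposure(model, pop, 0.25)
  t_hi <- calibrate_exposure(model, pop, 0.50)
  expect_lt(t_lo, t_hi)

  # zero-weight model: target 1 - exp(-1) at exposure 1/baseline_rate
  flat <- specificity_model(peptide_length = 11L, baseline_rate = 2)
  t_flat <- calibrate_exposure(flat, pop, 1 - exp(-1))
  expect_equal(t_flat, 1 / 2, tolerance = 1e-6)
})

test_that("library sampling respects each design's support", {
  # defined, no dispersion: near-equal counts summing to n_cells
  dd <- library_design("defined", peptide_length = 11L,
                       members = c("AAAAAYAAAAA", "CCCCCYCCCCC", "DDDDDYDDDDD"))
  cfgd <- simulation_config(dd, n_cells = 9000, seed = 63L)
  popd <- sample_library(cfgd)
  expect_equal(sum(popd), 9000L)
  expect_true(all(abs(popd - 3000) < 300))

  # degenerate: NNS-translatable alphabet only, fixed central Tyr
  dg <- x5yx5_design()
  cfgg <- simulation_config(dg, n_cells = 5000, seed = 64L)
  popg <- sample_library(cfgg)
  peps <- names(popg)
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY*]{11}$", peps)))
  expect_true(all(substr(peps, 6, 6) == "Y"))

  # scanning: support is exactly reference + single mutants (incl. amber)
  ds <- src_scanning_design()
  cfgs <- simulation_config(ds, n_cells = 50000, seed = 65L)
  pops <- sample_library(cfgs)
  ref <- strsplit(SRC_REF, "")[[1]]
  ndiff <- vapply(strsplit(names(pops), ""),
                  function(x) sum(x != ref), integer(1))
  expect_true(all(ndiff <= 1L))
  # with 5e4 cells over 221 variants, the whole support is observed
  expect_equal(length(pops), 11L * 20L + 1L)
})

test_that("selection follows the phosphorylation and capture probabilities", {
  d <- library_design("defined", peptide_length = 11L,
                      members = c("AAAAAYAAAAA", "CCCCCYCCCCC"))
  cfg <- simulation_config(d, n_cells = 2e5, capture_efficiency = 1,
                           background_capture = 0, seed = 66L)
  pop <- sample_library(cfg)

  # p = 1 for everyone, perfect capture: sorted == population
  hot <- specificity_model(peptide_length = 11L, baseline_rate = 1e6)
  sel1 <- simulate_selection(pop, hot, cfg)
  expect_identical(sel1$sorted, pop)

  # p = 0, no background: sorted empty
  cold <- specificity_model(peptide_length = 11L, baseline_rate = 1)
  cold$exposure_time <- 0
  sel0 <- simulate_selection(pop, cold, cfg)
  expect_length(sel0$sorted, 0L)

  # p 0.8 vs 0.2 at equal abundance: sorted ratio ~ 4:1
  m <- specificity_model(peptide_length = 11L, baseline_rate = 1)
  m$weights["A", 1] <- log(-log(1 - 0.8))   # p = 0.8 for the A... peptide
  m$weights["C", 1] <- log(-log(1 - 0.2))   # p = 0.2 for the C... peptide
  sel <- simulate_selection(pop, m, cfg)
  ratio <- sel$sorted[["AAAAAYAAAAA"]] / sel$sorted[["CCCCCYCCCCC"]]
  n <- pop[["AAAAAYAAAAA"]]
  se <- 4 * sqrt(0.8 * 0.2 / n + 0.2 * 0.8 / n)  # crude propagation
  expect_lt(abs(ratio - 4), 5 * se + 0.1)
})

test_that("expected enrichment matches the capture-probability formula", {
  d <- library_design("defined", peptide_length = 11L,
                      members = c("AAAAAYAAAAA", "CCCCCYCCCCC"))
  cfg <- simulation_config(d, n_cells = 1000, capture_efficiency = 0.9,
                           background_capture = 0.01, seed = 67L)
  pop <- setNames(c(500L, 500L), d$members)
  m <- specificity_model(peptide_length = 11L)
  m$weights["A", 1] <- 1
  p <- phosphorylation_probability(d$members, m)
  cap <- p * 0.9 + (1 - p) * 0.01
  want <- cap / (sum(cap * pop) / sum(pop))
  expect_equal(unname(expected_enrichment(pop, m, cfg)), unname(want),
               tolerance = 1e-12)
})

test_that("identical configs give byte-identical FASTQ and truth outputs", {
  d <- x5yx5_design()
  cfg <- simulation_config(d, n_cells = 500, reads_per_sample = 300,
                           sequencing_error_rate = 0.01, seed = 68L)
  pop <- sample_library(cfg)
  o1 <- emit_fastq(pop, cfg, file.path(tempdir(), "det_a"), gzip = FALSE)
  o2 <- emit_fastq(pop, cfg, file.path(tempdir(), "det_b"), gzip = FALSE)
  expect_identical(readLines(o1$r1), readLines(o2$r1))
  expect_identical(readLines(o1$r2), readLines(o2$r2))
  expect_identical(readLines(o1$truth), readLines(o2$truth))
  expect_error(simulation_config(d, reads_per_sample = 0), "reads_per_sample")
})

test_that("reads survive flank matching at a 1% error rate", {
  d <- x5yx5_design()
  cfg <- simulation_config(d, n_cells = 1000, reads_per_sample = 1000,
                           sequencing_error_rate = 0.01, seed = 69L)
  pop <- sample_library(cfg)
  out <- emit_fastq(pop, cfg, file.path(tempdir(), "err1"), gzip = TRUE)
  res <- process_sample(out$r1, out$r2, d)
  # binomial expectation: each anchor fails when it carries >= 2 of the
  # injected substitutions (1-mismatch tolerance)
  p_anchor <- function(k, e) pbinom(1, k, e)
  p_pass <- p_anchor(36, 0.01) * p_anchor(37, 0.01)
  obs <- res$qc$status_counts$ok / 1000
  expect_gt(obs, p_pass - 4 * sqrt(p_pass * (1 - p_pass) / 1000))
  expect_gte(obs, 0.85)
})
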
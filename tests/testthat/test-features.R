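test_that("peaks of a clean two-bump trace are found at the bump centers", {
  cfg <- sim_config()
  y <- simulate_waveform(cfg, 30, noise_sd = 0)
  pk <- detect_applanation_peaks(y)
  expect_lte(abs(pk$p1 - 120), 2)
  expect_lte(abs(pk$p2 - 280), 2)
  expect_true(pk$p1 < pk$trough && pk$trough < pk$p2)
})

test_that("a monotone ramp raises a no-peaks error", {
  expect_error(detect_applanation_peaks(seq_len(400)), "no-peaks")
  expect_error(detect_applanation_peaks(rnorm(5)), "invalid-argument")
})

test_that("peak detection is stable under 2% noise", {
  cfg <- sim_config()
  clean <- simulate_waveform(cfg, 30, noise_sd = 0)
  set.seed(99)
  hits <- vapply(seq_len(100), function(i) {
    y <- clean + rnorm(400, 0, 0.02 * 611.54)
    pk <- detect_applanation_peaks(y)
    abs(pk$p1 - 120) <= 3 && abs(pk$p2 - 280) <= 3
  }, logical(1))
  expect_gte(sum(hits), 99)
})

test_that("the worked inter-peak segment yields Monot1-2 of exactly 2", {
  y <- c(10, 8, 9, 5, 4, 6, 5, 7, 10)
  pk <- list(p1 = 1, trough = 5, p2 = 9)
  expect_identical(monot12(y, pk), 2)
  expect_identical(oracle_monot(y, 1, 5, 9), 2)
})

test_that("a strictly V-shaped segment has Monot1-2 of 0", {
  y <- c(10, 7, 4, 2, 1, 2, 4, 7, 10)
  expect_identical(monot12(y, list(p1 = 1, trough = 5, p2 = 9)), 0)
})

test_that("monot12 equals the brute-force oracle on random segments", {
  set.seed(12)
  pairs <- t(vapply(seq_len(1000), function(i) {
    seg <- random_segment(sample(10:60, 1))
    c(monot12(seg$y, list(p1 = seg$p1, trough = seg$trough, p2 = seg$p2)),
      oracle_monot(seg$y, seg$p1, seg$trough, seg$p2))
  }, numeric(2)))
  # tolerance covers only summation order; the adverse sets are identical
  expect_lt(max(abs(pairs[, 1] - pairs[, 2]) / pmax(1, pairs[, 2])), 1e-12)
})

test_that("monot12 is translation invariant and 1-homogeneous", {
  set.seed(13)
  for (i in seq_len(50)) {
    seg <- random_segment(40)
    pk <- list(p1 = seg$p1, trough = seg$trough, p2 = seg$p2)
    v <- monot12(seg$y, pk)
    expect_equal(monot12(seg$y + 57.3, pk), v, tolerance = 1e-9)
    expect_equal(monot12(3.5 * seg$y, pk), 3.5 * v, tolerance = 1e-9)
    expect_gte(v, 0)
  }
})

test_that("monot12 validates its peak pair and supports arc length", {
  y <- c(10, 8, 9, 5, 4, 6, 5, 7, 10)
  expect_error(monot12(y, list(p1 = 5, trough = 2, p2 = 9)),
               "invalid-argument")
  # two adverse unit steps -> arc length 2 * sqrt(2)
  expect_equal(monot12(y, list(p1 = 1, trough = 5, p2 = 9),
                       method = "arclength"),
               2 * sqrt(2), tolerance = 1e-12)
})

test_that("surrogate descriptors match simulator ground truth on clean traces", {
  cfg <- sim_config()
  y <- simulate_waveform(cfg, 0, noise_sd = 0)
  f <- surrogate_descriptors(y, detect_applanation_peaks(y))
  expect_lt(abs(f$h1 - 511.54), 2)   # 611.54 minus baseline 100
  expect_lt(abs(f$h2 - 426.29), 2)
  expect_identical(f$Aindex, 10)
  expect_identical(f$Bindex, 10)
  expect_lt(f$Aplhf, 0.05)
  expect_equal(f$h11, f$h1 / 2, tolerance = 1e-12)
  expect_equal(f$h21, f$h2 / 2, tolerance = 1e-12)
  expect_gte(f$w1, 1)
  expect_gte(f$p1area, 0)
})

test_that("amplitude scaling doubles heights, areas and slopes but not widths", {
  cfg <- sim_config()
  y <- simulate_waveform(cfg, 20, noise_sd = 0)
  pk <- detect_applanation_peaks(y)
  # scale about the baseline so the height cut positions are preserved
  base <- median(y[1:50])
  y2 <- base + 2 * (y - base)
  f1 <- surrogate_descriptors(y, pk)
  f2 <- surrogate_descriptors(y2, pk)
  for (nm in c("h1", "h2", "dive1", "dive2", "p1area", "p2area",
               "uslope1", "dslope2", "slew1", "mslew2")) {
    expect_equal(f2[[nm]], 2 * f1[[nm]], tolerance = 1e-6)
  }
  for (nm in c("w1", "w2", "path1", "path2")) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6)
  }
})

test_that("degenerate peaks raise a feature error naming the field", {
  y <- c(rep(10, 50), rep(5, 350))
  expect_error(surrogate_descriptors(y, list(p1 = 60, trough = 200, p2 = 300)),
               "h1")
})

test_that("design matrix has 41 named columns and excludes h11/h21", {
  co <- quick_cohort(n_eyes = 25, seed = 6)
  ft <- feature_table(average_replicates(co$records))
  d <- assemble_design_matrix(ft, co$covariates)
  expect_equal(ncol(d$X), 41)
  expect_false(any(c("h11", "h21") %in% colnames(d$X)))
  expect_true(all(c("age", "AL", "SERE", "CH", "CRF", "monot12") %in%
                  colnames(d$X)))
  expect_equal(nrow(d$X), 25)
  expect_equal(colMeans(d$X_std), rep(0, 41), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the published variable list keeps keratometry out of the regression
  expect_false("keratometry" %in% colnames(d$X))
  d2 <- assemble_design_matrix(ft, co$covariates, include_keratometry = TRUE)
  expect_equal(ncol(d2$X), 42)
})

test_that("assembly errors name eyes with missing covariates or PRAA", {
  co <- quick_cohort(n_eyes = 5, seed = 6)
  ft <- feature_table(average_replicates(co$records))
  expect_error(assemble_design_matrix(ft, co$covariates[-2, ]),
               co$covariates$eye_id[2])
  cov2 <- co$covariates
  cov2$PRAA[3] <- NA
  expect_error(assemble_design_matrix(ft, cov2), cov2$eye_id[3])
})
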
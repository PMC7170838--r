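test_that("AICc formula matches hand arithmetic and base R's AIC convention", {
  # n = 20, rss = 10, two slopes (p = 4)
  hand <- 20 * log(2 * pi * 10 / 20) + 20 + 2 * 4 + 2 * 4 * 5 / (20 - 4 - 1)
  expect_equal(aicc(20, 10, 2), hand, tolerance = 1e-12)

  set.seed(2)
  x1 <- rnorm(30); x2 <- rnorm(30)
  y <- 1 + x1 - x2 + rnorm(30)
  fit <- lm(y ~ x1 + x2)
  rss <- sum(residuals(fit)^2)
  p <- 4
  expect_equal(aicc(30, rss, 2),
               AIC(fit) + 2 * p * (p + 1) / (30 - p - 1), tolerance = 1e-9)

  # penalty monotonicity at equal rss; correction vanishes for large n
  expect_gt(aicc(20, 10, 3), aicc(20, 10, 2))
  aic_plain <- function(n, rss, k) n * log(2 * pi * rss / n) + n + 2 * (k + 2)
  expect_lt(abs(aicc(1e6, 10, 2) - aic_plain(1e6, 10, 2)), 1e-4)

  expect_error(aicc(20, 0, 2), "degenerate-fit")
  expect_error(aicc(6, 10, 3), "saturation")
})

test_that("lasso screen returns exactly k names and finds planted signals", {
  set.seed(4)
  hits <- vapply(seq_len(20), function(s) {
    set.seed(s)
    X <- matrix(rnorm(200 * 30), 200, 30,
                dimnames = list(NULL, paste0("v", 1:30)))
    y <- 3 * X[, "v3"] - 2.5 * X[, "v11"] + 2 * X[, "v27"] + rnorm(200)
    sel <- lasso_screen(X, y, k = 20)
    expect_length(sel, 20)
    all(c("v3", "v11", "v27") %in% sel)
  }, logical(1))
  expect_true(all(hits))
})

test_that("lasso screen edge cases: k equal to columns, constants, k too big", {
  set.seed(5)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("c", 1:6)))
  y <- rnorm(50)
  expect_setequal(lasso_screen(X, y, k = 6), colnames(X))
  Xc <- cbind(X, const = 1)
  expect_warning(sel <- lasso_screen(Xc, y, k = 6), "constant")
  expect_false("const" %in% sel)
  expect_error(suppressWarnings(lasso_screen(Xc, y, k = 7)),
               "invalid-argument")
})

test_that("sweep search equals naive refits exactly for 3 candidates", {
  set.seed(6)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] + rnorm(40)
  sel <- exhaustive_aicc_search(X, y, c("a", "b", "c"), return_all = TRUE)
  expect_equal(sel$n_models_evaluated, 8)
  for (mask in 0:7) {
    idx <- which(bitwAnd(mask, 2^(0:2)) != 0)
    expect_equal(sel$all_aicc[mask + 1], oracle_subset_aicc(X, y, idx),
                 tolerance = 1e-8)
  }
  naive_best <- which.min(vapply(0:7, function(mask) {
    oracle_subset_aicc(X, y, which(bitwAnd(mask, 2^(0:2)) != 0))
  }, numeric(1))) - 1
  got_mask <- sum(2^(match(sel$best$subset, c("a", "b", "c")) - 1))
  expect_identical(got_mask, as.numeric(naive_best))
})

test_that("a planted two-variable model is recovered among decoys", {
  set.seed(7)
  X <- matrix(rnorm(100 * 12), 100, 12,
              dimnames = list(NULL, paste0("x", 1:12)))
  y <- 2 * X[, "x1"] - 3 * X[, "x2"] + rnorm(100, 0, 0.5)
  sel <- exhaustive_aicc_search(X, y, colnames(X))
  expect_true(all(c("x1", "x2") %in% sel$best$subset))
  ct <- sel$best$coefficients
  expect_equal(ct$estimate[ct$term == "x1"], 2, tolerance = 0.15)
  expect_equal(ct$estimate[ct$term == "x2"], -3, tolerance = 0.15)
  # AICc of the best model beats explicit refits of other subsets
  expect_lte(sel$best$aicc, refit_subset(X, y, c("x1", "x2", "x3"))$aicc)
  expect_lte(sel$best$aicc, refit_subset(X, y, "x1")$aicc)
  # consistency between sweep rss and the refit
  expect_equal(sel$best$aicc, aicc(100, sel$best$rss, length(sel$best$subset)),
               tolerance = 1e-9)
})

test_that("empty candidate set gives the intercept-only model", {
  set.seed(8)
  X <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "z"))
  y <- rnorm(30)
  sel <- exhaustive_aicc_search(X, y, character(0))
  expect_equal(sel$n_models_evaluated, 1)
  expect_length(sel$best$subset, 0)
  expect_equal(sel$best$rss, sum((y - mean(y))^2), tolerance = 1e-9)
})

test_that("linearly dependent candidates are dropped with a warning", {
  set.seed(9)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  X <- cbind(X, d = X[, "a"] + X[, "b"])
  y <- rnorm(50)
  expect_warning(sel <- exhaustive_aicc_search(X, y, colnames(X)),
                 "dependent")
  expect_lt(length(sel$candidates), 4)
})

test_that("univariate scan matches single regressions and flags constants", {
  set.seed(10)
  x <- rnorm(40)
  X <- cbind(exact = x, noise = rnorm(40), flat = 1)
  y <- 5 * x
  expect_error(univariate_scan(X[1:2, ], y[1:2]), "at least 3")
  tab <- suppressWarnings(univariate_scan(X, y))  # exact fit warns in summary
  expect_equal(nrow(tab), 3)
  expect_equal(tab$coefficient[tab$variable == "exact"], 5, tolerance = 1e-9)
  expect_lt(tab$p_value[tab$variable == "exact"], 1e-12)
  expect_true(tab$constant[tab$variable == "flat"])
  expect_true(is.na(tab$coefficient[tab$variable == "flat"]))
})

test_that("univariate p-values are calibrated under the null", {
  set.seed(11)
  p <- vapply(seq_len(400), function(i) {
    x <- rnorm(50)
    univariate_scan(cbind(x = x), rnorm(50))$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("nested ANOVA agrees with stats::anova and enforces nesting", {
  set.seed(12)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, "a"] + 0.5 * X[, "b"] + rnorm(60)
  small <- refit_subset(X, y, "a")
  large <- refit_subset(X, y, c("a", "b", "c"))
  got <- anova_nested(small, large)
  ref <- stats::anova(lm(y ~ X[, "a"]), lm(y ~ X[, c("a", "b", "c")]))
  expect_equal(got$F, ref$F[2], tolerance = 1e-9)
  expect_equal(got$p, ref$`Pr(>F)`[2], tolerance = 1e-9)
  expect_error(anova_nested(large, small), "nested")
  expect_error(anova_nested(refit_subset(X, y, "b"),
                            refit_subset(X, y, c("a", "c"))), "nested")
})

test_that("nested ANOVA detects a strong added effect", {
  set.seed(13)
  hits <- vapply(seq_len(40), function(i) {
    x1 <- rnorm(80); x2 <- rnorm(80)
    y <- x1 + 1.5 * x2 + rnorm(80)
    X <- cbind(x1 = x1, x2 = x2)
    anova_nested(refit_subset(X, y, "x1"),
                 refit_subset(X, y, c("x1", "x2")))$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("selection results serialize to JSON and CSV", {
  set.seed(14)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- X[, 1] + rnorm(50)
  sel <- exhaustive_aicc_search(X, y, colnames(X))
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_selection_result(sel, jp, cp)
  payload <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(payload$aicc, sel$best$aicc, tolerance = 1e-9)
  expect_equal(nrow(read.csv(cp)), nrow(sel$aicc_table))
})
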
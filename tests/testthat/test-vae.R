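test_that("parameter count matches the closed-form layer sum", {
  arch <- vae_arch()
  hand <- (400 * 40 + 40) + (40 * 20 + 20) +
    2 * (20 * 2 + 2) +                       # mu and log-variance heads
    (2 * 20 + 20) + (20 * 40 + 40) + (40 * 400 + 400)
  expect_identical(vae_n_params(arch), as.numeric(hand))
  got <- sum(vapply(init_vae(arch, 1)$params, length, numeric(1)))
  expect_identical(got, as.numeric(hand))
})

test_that("initialization is seed-reproducible and validates the arch", {
  a <- init_vae(vae_arch(), seed = 5)
  b <- init_vae(vae_arch(), seed = 5)
  expect_identical(a$params, b$params)
  expect_error(vae_arch(latent_dim = 0), "config error")
  y <- reconstruct(suppressWarnings(train_vae(a, matrix(rnorm(12 * 400), 12),
                                              epochs = 1, seed = 1)),
                   rnorm(400))
  expect_length(y, 400)
  expect_error(vae_encode(a, rnorm(200)), "config error")
})

test_that("KL closed form matches quadrature and its exact values", {
  expect_identical(kl_standard_normal(list(mu = c(0, 0), logvar = c(0, 0))), 0)
  expect_equal(kl_standard_normal(list(mu = c(1, 0), logvar = c(0, 0))), 0.5)
  expect_error(kl_standard_normal(list(mu = c(NA, 0), logvar = c(0, 0))),
               "invalid-argument")
  set.seed(17)
  for (i in seq_len(25)) {
    mu <- rnorm(2, 0, 2)
    lv <- rnorm(2, 0, 1)
    expect_equal(kl_standard_normal(list(mu = mu, logvar = lv)),
                 oracle_kl_quadrature(mu, lv), tolerance = 1e-6)
  }
})

test_that("analytic gradients match finite differences", {
  arch <- vae_arch(input_dim = 12, encoder_hidden = c(6, 4), latent_dim = 2)
  m <- init_vae(arch, seed = 3)
  set.seed(5)
  X <- matrix(rnorm(5 * 12), 5, 12)
  eps <- matrix(rnorm(5 * 2), 5, 2)
  g <- praawave:::.vae_grad(m, X, eps, beta = 0.7)
  h <- 1e-6
  for (nm in names(m$params)) {
    for (i in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
      up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + h
      dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - h
      num <- (praawave:::.vae_grad(up, X, eps, 0.7)$loss -
              praawave:::.vae_grad(dn, X, eps, 0.7)$loss) / (2 * h)
      expect_equal(g$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("elbo components: KL term is the batch mean; beta scales linearly", {
  co <- quick_cohort(n_eyes = 10, seed = 2)
  tr <- co$records$traces[1:12, ]
  m <- train_vae(init_vae(vae_arch(), 1), tr, epochs = 2, seed = 1)
  l1 <- elbo_loss(tr, m, beta = 1)
  codes <- vae_encode(m, tr)
  expect_equal(l1$kl,
               mean(kl_standard_normal(list(mu = codes$mu,
                                            logvar = codes$logvar))),
               tolerance = 1e-9)
  l2 <- elbo_loss(tr, m, beta = 2)
  expect_equal(l2$total - l2$reconstruction,
               2 * (l1$total - l1$reconstruction), tolerance = 1e-9)
  expect_gte(l1$reconstruction, 0)
  expect_gte(l1$kl, 0)
})

test_that("training reduces the loss, is deterministic, and epochs=0 is a no-op", {
  co <- simulate_cohort(sim_config(n_eyes = 200, n_replicates = 1, seed = 14))
  tr <- co$records$traces
  m0 <- init_vae(vae_arch(), seed = 4)
  expect_identical(train_vae(m0, tr, epochs = 0), m0)
  m1 <- train_vae(m0, tr, epochs = 40, seed = 9)
  expect_lt(m1$history$total[40], m1$history$total[1])
  m2 <- train_vae(m0, tr, epochs = 40, seed = 9)
  expect_identical(m1$params, m2$params)
  expect_error(train_vae(m0, tr[1:5, ], epochs = 1), "at least 10")
})

test_that("reconstruction is robust and approximately idempotent", {
  co <- simulate_cohort(sim_config(n_eyes = 150, n_replicates = 1, seed = 15))
  m <- train_vae(init_vae(vae_arch(), 2), co$records$traces,
                 epochs = 120, seed = 3)
  y <- co$records$traces[7, ]
  r1 <- reconstruct(m, y)
  r2 <- reconstruct(m, r1)
  d1 <- sqrt(sum((r1 - y)^2))
  d2 <- sqrt(sum((r2 - r1)^2))
  expect_lt(d2, 0.1 * d1)
  # constant-zero input: finite output, no error
  expect_true(all(is.finite(reconstruct(m, rep(0, 400)))))
  # untrained model warns and proceeds
  expect_warning(r <- reconstruct(init_vae(vae_arch(), 1), y), "untrained")
  expect_length(r, 400)
})

test_that("PRAA axis recovers an exact linear latent relation", {
  set.seed(8)
  praa <- runif(40, 100, 170)
  mu <- cbind(praa / 10, 0)
  ax <- fit_praa_axis(mu, praa)
  expect_equal(ax$direction, c(1, 0), tolerance = 1e-9)
  expect_equal(ax$slope, 10, tolerance = 1e-9)
  expect_equal(ax$intercept, 0, tolerance = 1e-6)
  expect_error(fit_praa_axis(mu[1:2, ], praa[1:2]), "at least 3")
  expect_error(fit_praa_axis(matrix(1, 10, 2), praa[1:10]), "degenerate-fit")
})

test_that("permuting PRAA labels collapses the fitted slope", {
  set.seed(18)
  n <- 2000
  praa <- runif(n, 100, 170)
  mu <- cbind(praa / 10 + rnorm(n, 0, 0.05), rnorm(n, 0, 2))
  real_slope <- fit_praa_axis(mu, praa)$slope
  perm_slopes <- vapply(seq_len(20), function(i) {
    fit_praa_axis(mu, sample(praa))$slope
  }, numeric(1))
  expect_lt(max(perm_slopes), real_slope / 10)
})

test_that("latent traversal is ordered, centered, and degenerates correctly", {
  co <- simulate_cohort(sim_config(n_eyes = 120, n_replicates = 1, seed = 16))
  m <- train_vae(init_vae(vae_arch(), 2), co$records$traces,
                 epochs = 100, seed = 3)
  codes <- vae_encode(m, co$records$traces)
  ax <- fit_praa_axis(codes$mu, co$covariates$PRAA)
  fr <- traverse(m, ax, span = 2, n_frames = 11)
  expect_equal(dim(fr), c(11, 400))
  # predicted PRAA decreases along the frames
  expect_true(all(diff(attr(fr, "praa_pred")) <= 1e-9))
  # middle frame decodes the latent center
  center_dec <- vae_decode(m, colMeans(m$train_mu))
  expect_equal(as.numeric(fr[6, ]), as.numeric(center_dec), tolerance = 1e-9)
  # smoothness: consecutive steps are smaller than the total sweep
  l2 <- function(a, b) sqrt(sum((a - b)^2))
  total <- l2(fr[1, ], fr[11, ])
  for (i in 1:10) expect_lt(l2(fr[i, ], fr[i + 1, ]), total)
  # span 0: all frames identical
  fr0 <- traverse(m, ax, span = 0, n_frames = 5)
  expect_equal(max(abs(sweep(fr0, 2, fr0[1, ]))), 0, tolerance = 1e-12)
  # reversing the axis reverses the frame order
  ax_rev <- ax
  ax_rev$direction <- -ax$direction
  fr_rev <- traverse(m, ax_rev, span = 2, n_frames = 11)
  expect_equal(fr_rev, fr[11:1, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(traverse(m, ax, n_frames = 1), "n_frames")
})

test_that("animation export writes frames that round-trip via CSV", {
  co <- simulate_cohort(sim_config(n_eyes = 60, n_replicates = 1, seed = 19))
  m <- train_vae(init_vae(vae_arch(), 2), co$records$traces,
                 epochs = 30, seed = 3)
  ax <- fit_praa_axis(vae_encode(m, co$records$traces)$mu,
                      co$covariates$PRAA)
  fr <- traverse(m, ax, span = 1, n_frames = 7)
  path <- withr::local_tempfile(fileext = ".tiff")
  out <- export_animation(fr, path)
  expect_true(file.exists(out$tiff))
  expect_equal(length(tiff::readTIFF(out$tiff, all = TRUE)), 7)
  back <- read_animation_frames(out$csv)
  expect_equal(back, unclass(fr), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(export_animation(fr[1, , drop = FALSE], path), "2 frames")
})

test_that("checkpoints round-trip through JSON", {
  co <- simulate_cohort(sim_config(n_eyes = 40, n_replicates = 1, seed = 22))
  m <- train_vae(init_vae(vae_arch(), 2), co$records$traces,
                 epochs = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_vae_checkpoint(m, path)
  m2 <- load_vae_checkpoint(path)
  y <- co$records$traces[3, ]
  expect_equal(reconstruct(m2, y), reconstruct(m, y), tolerance = 1e-9)
})
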
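# Independent oracles and small fixture builders used across the suite.

# Brute-force adverse-increment sum: literal loop over the definition,
# independent of the vectorized implementation.
oracle_monot <- function(y, p1, trough, p2) {
  total <- 0
  for (i in p1:(trough - 1)) total <- total + max(0, y[i + 1] - y[i])
  for (i in trough:(p2 - 1)) total <- total + max(0, y[i] - y[i + 1])
  total
}

# Random inter-peak segment with its peak/trough indices.
random_segment <- function(len = 30) {
  p1 <- 1
  p2 <- len
  y <- cumsum(rnorm(len))
  y[1] <- max(y) + abs(rnorm(1)) + 1  # make the ends the maxima
  y[len] <- max(y) + abs(rnorm(1)) + 1
  trough <- which.min(y[2:(len - 1)]) + 1
  list(y = y, p1 = p1, trough = trough, p2 = p2)
}

# KL(N(mu, exp(lv)) || N(0, 1)) per dimension by numerical quadrature.
oracle_kl_quadrature <- function(mu, logvar) {
  sum(vapply(seq_along(mu), function(d) {
    s <- exp(logvar[d] / 2)
    stats::integrate(function(x) {
      q <- stats::dnorm(x, mu[d], s)
      q * (stats::dnorm(x, mu[d], s, log = TRUE) - stats::dnorm(x, log = TRUE))
    }, mu[d] - 12 * s - 12, mu[d] + 12 * s + 12, rel.tol = 1e-10)$value
  }, numeric(1)))
}

# Naive per-subset least-squares refit: AICc via an lm.fit of the raw columns.
oracle_subset_aicc <- function(X, y, subset_idx) {
  n <- length(y)
  Z <- cbind(1, X[, subset_idx, drop = FALSE])
  fit <- .lm.fit(Z, y)
  rss <- sum(fit$residuals^2)
  p <- length(subset_idx) + 2
  n * log(2 * pi * rss / n) + n + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# Small default-shaped cohort for quick tests.
quick_cohort <- function(n_eyes = 30, seed = 1, ...) {
  simulate_cohort(sim_config(n_eyes = n_eyes, seed = seed, ...))
}
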
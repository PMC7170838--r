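# Seeded generator of ORA-like applanation cohorts with planted ground truth.
# Every downstream stage (filtering, averaging, denoising, feature extraction,
# model selection) is testable against the planted values.

#' Default covariate moments for the synthetic cohort
#'
#' Per-eye covariates are drawn as independent Gaussians with these moments:
#' age 51.0 +/- 21 y, axial length 24.6 +/- 1.7 mm, spherical equivalent
#' -1.91 +/- 4.1 D, keratometry 8.2 +/- 0.5 mm, corneal hysteresis
#' 10.26 +/- 1.0 mmHg, corneal resistance factor 9.85 +/- 1.3 mmHg.
#'
#' @return A data.frame with columns `variable`, `mean`, `sd`.
#' @export
default_covariate_moments <- function() {
  data.frame(
    variable = c("age", "AL", "SERE", "keratometry", "CH", "CRF"),
    mean = c(51.0, 24.6, -1.91, 8.2, 10.26, 9.85),
    sd = c(21, 1.7, 4.1, 0.5, 1.0, 1.3),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic ORA cohort simulator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a bimodal
#' applanation trace (two Gaussian bumps over a flat baseline), retrogressive
#' wiggles of controllable total magnitude confined to the inter-peak
#' interval, additive i.i.d. Gaussian sensor noise, a quality index per
#' measurement, per-eye covariates, and a linear PRAA link with planted
#' coefficients.
#'
#' Peak heights are absolute trace maxima (the bump amplitude is
#' `height - baseline`). `retro_mean`/`retro_sd` set the distribution
#' (Gaussian truncated at zero) of each eye's planted Monot1-2 magnitude.
#' `qi_low_fraction` forces that fraction of measurements to a quality index
#' at or below 7.5 so the quality filter can be exercised.
#'
#' `praa_coefs` is a named vector over predictor names (covariate names such
#' as `"AL"`, or waveform feature names such as `"monot12"`, `"h1"`); PRAA is
#' `praa_intercept + sum(coef * predictor) + N(0, praa_noise_sd)`, where the
#' `monot12` predictor is the eye's true (noise-free) Monot1-2.
#'
#' @param n_eyes Number of eyes.
#' @param n_replicates Measurements per eye (default 3).
#' @param trace_len Samples per trace (default 400).
#' @param peak1_center,peak2_center Sample indices of the applanation peaks.
#' @param peak_width Gaussian bump standard deviation, in samples.
#' @param baseline Flat baseline level, signal units.
#' @param peak1_height_mean,peak1_height_sd,peak2_height_mean,peak2_height_sd
#'   Per-eye peak-height distribution (absolute trace maxima), signal units.
#' @param retro_mean,retro_sd Moments of the planted retrogressive magnitude.
#' @param noise_sd Per-sample additive noise standard deviation, signal units.
#' @param tremor_rho_sd Spread of the per-eye tremor intensity (ratio of the
#'   high-frequency texture amplitude to the local slope magnitude; drawn as
#'   `|N(0, tremor_rho_sd)|` capped at `tremor_cap`).
#' @param tremor_cap Upper bound of the tremor intensity ratio (< 1 keeps the
#'   inter-peak segment monotone apart from the planted reversals).
#' @param tremor_period Tremor oscillation period, samples.
#' @param qi_mean,qi_sd Quality-index moments (truncated to `[0, 10]`).
#' @param qi_low_fraction Fraction of measurements forced to QI <= 7.5.
#' @param covariate_moments Data frame as from [default_covariate_moments()].
#' @param praa_intercept Intercept of the PRAA link, degrees.
#' @param praa_coefs Named numeric vector of planted coefficients.
#' @param praa_noise_sd Residual PRAA noise, degrees.
#' @param n_wiggles Number of retrogressive tent reversals.
#' @param wiggle_halfwidth Ramp length of each reversal, samples.
#' @param seed Integer seed; equal config + seed gives a bit-identical cohort.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_eyes = 54,
                       n_replicates = 3,
                       trace_len = 400,
                       peak1_center = 120,
                       peak2_center = 280,
                       peak_width = 25,
                       baseline = 100,
                       peak1_height_mean = 611.54, peak1_height_sd = 63.00,
                       peak2_height_mean = 526.29, peak2_height_sd = 73.74,
                       retro_mean = 31.55, retro_sd = 25.97,
                       noise_sd = 2,
                       tremor_rho_sd = 0.35, tremor_cap = 0.9,
                       tremor_period = 8,
                       qi_mean = 8.81, qi_sd = 0.6,
                       qi_low_fraction = 0,
                       covariate_moments = default_covariate_moments(),
                       praa_intercept = 202.6,
                       praa_coefs = c(AL = -2.37, monot12 = -0.31),
                       praa_noise_sd = 10,
                       n_wiggles = 4,
                       wiggle_halfwidth = 6,
                       seed = 1L) {
  cfg <- list(
    n_eyes = as.integer(n_eyes), n_replicates = as.integer(n_replicates),
    trace_len = as.integer(trace_len),
    peak1_center = as.integer(peak1_center),
    peak2_center = as.integer(peak2_center),
    peak_width = peak_width, baseline = baseline,
    peak1_height_mean = peak1_height_mean, peak1_height_sd = peak1_height_sd,
    peak2_height_mean = peak2_height_mean, peak2_height_sd = peak2_height_sd,
    retro_mean = retro_mean, retro_sd = retro_sd,
    noise_sd = noise_sd,
    tremor_rho_sd = tremor_rho_sd, tremor_cap = tremor_cap,
    tremor_period = tremor_period,
    qi_mean = qi_mean, qi_sd = qi_sd,
    qi_low_fraction = qi_low_fraction,
    covariate_moments = covariate_moments,
    praa_intercept = praa_intercept, praa_coefs = praa_coefs,
    praa_noise_sd = praa_noise_sd,
    n_wiggles = as.integer(n_wiggles),
    wiggle_halfwidth = as.integer(wiggle_halfwidth),
    seed = as.integer(seed)
  )
  if (!(cfg$peak1_center > 0 && cfg$peak1_center < cfg$peak2_center &&
        cfg$peak2_center < cfg$trace_len)) {
    stop("invalid-config: need 0 < peak1_center < peak2_center < trace_len")
  }
  sds <- c(cfg$peak1_height_sd, cfg$peak2_height_sd, cfg$retro_sd,
           cfg$noise_sd, cfg$qi_sd, cfg$praa_noise_sd,
           covariate_moments$sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("invalid-config: all standard deviations must be finite and >= 0")
  }
  if (cfg$n_replicates < 1) stop("invalid-config: n_replicates must be >= 1")
  if (cfg$n_wiggles < 1) stop("invalid-config: n_wiggles must be >= 1")
  if (cfg$wiggle_halfwidth < 1) {
    stop("invalid-config: wiggle_halfwidth must be >= 1")
  }
  room <- (cfg$peak2_center - cfg$peak1_center) / 2
  if (ceiling(cfg$n_wiggles / 2) * (2 * cfg$wiggle_halfwidth + 3) + 4 >= room) {
    stop("invalid-config: reversals do not fit between the peaks")
  }
  if (cfg$qi_low_fraction < 0 || cfg$qi_low_fraction > 1) {
    stop("invalid-config: qi_low_fraction must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# Smooth bimodal base: baseline plus two Gaussian bumps.
.base_trace <- function(cfg, peak_heights) {
  i <- seq_len(cfg$trace_len)
  a1 <- peak_heights[1] - cfg$baseline
  a2 <- peak_heights[2] - cfg$baseline
  cfg$baseline +
    a1 * exp(-0.5 * ((i - cfg$peak1_center) / cfg$peak_width)^2) +
    a2 * exp(-0.5 * ((i - cfg$peak2_center) / cfg$peak_width)^2)
}

# Per-eye high-frequency texture ("tremor"): a sinusoid whose amplitude is
# proportional to the local slope magnitude of the base. Because the
# amplitude ratio is below 1, the texture never reverses the direction of
# the underlying movement, so the inter-peak segment stays monotone apart
# from the planted reversals; an explicit clamp guarantees this exactly.
.flank_tremor <- function(base, rho, phase, period) {
  m <- abs(c(diff(base), 0))
  m <- .moving_avg(m, 5)
  rho * m * sin(2 * pi * seq_along(base) / period + phase)
}

# Enforce strict monotonicity of y on idx (direction -1 decreasing,
# +1 increasing); returns y with minimal clamping.
.enforce_monotone <- function(y, idx, direction) {
  for (i in idx[-1]) {
    lim <- y[i - 1] + direction * 1e-9
    if (direction < 0 && y[i] > lim) y[i] <- lim
    if (direction > 0 && y[i] < lim) y[i] <- lim
  }
  y
}

# Plant one retrogressive "tent" reversal of adverse total `contrib` with
# its base at sample a (occupying a..a+2r). On the descending side the
# up-ramp is the adverse half; on the ascending side the down-ramp is. Each
# adverse step is solved against the local step of the current profile, so
# the added adverse movement is exactly `contrib` whatever the shape
# underneath.
.plant_tent <- function(y, a, r, contrib, side) {
  d <- numeric(2 * r + 1)
  if (side < 0) {  # descending segment
    for (s in seq_len(r)) {
      u <- contrib / r - (y[a + s] - y[a + s - 1])
      d[s + 1] <- d[s] + u
    }
    f <- d[r + 1] / r
    for (s in seq_len(r)) d[r + 1 + s] <- d[r + 1] - s * f
  } else {         # ascending segment: adverse half is the fall
    fall <- vapply(seq_len(r), function(s) {
      contrib / r + (y[a + r + s] - y[a + r + s - 1])
    }, numeric(1))
    H <- sum(fall)
    for (s in seq_len(r)) d[s + 1] <- s * H / r
    for (s in seq_len(r)) d[r + 1 + s] <- H - sum(fall[seq_len(s)])
  }
  y[a:(a + 2 * r)] <- y[a:(a + 2 * r)] + d
  y
}

#' Simulate one ORA-like applanation trace
#'
#' Builds a smooth bimodal base (two Gaussian bumps over a flat baseline),
#' optionally adds a per-eye high-frequency tremor texture (amplitude
#' proportional to the local slope, so the inter-peak profile stays
#' monotone), then plants `n_wiggles` narrow triangular reversals around the
#' inter-peak trough whose amplitudes are solved so that the
#' adverse-increment (Monot1-2) total of the noise-free trace equals
#' `retro_magnitude` exactly, and finally adds i.i.d. Gaussian noise. Uses
#' the R random-number stream; seed it with [set.seed()] for
#' reproducibility.
#'
#' @param cfg A [sim_config()].
#' @param retro_magnitude Planted Monot1-2 magnitude, signal units (>= 0).
#' @param peak_heights Length-2 vector of absolute peak heights; defaults to
#'   the configured means.
#' @param noise_sd Noise standard deviation; defaults to `cfg$noise_sd`.
#' @param tremor_rho Tremor intensity ratio for this eye (0 = none).
#' @param tremor_phase Tremor phase, radians.
#' @param wiggle_jitter Integer offsets (length `n_wiggles`) perturbing the
#'   reversal positions.
#'
#' @return Numeric vector of length `cfg$trace_len`.
#' @export
simulate_waveform <- function(cfg, retro_magnitude,
                              peak_heights = c(cfg$peak1_height_mean,
                                               cfg$peak2_height_mean),
                              noise_sd = cfg$noise_sd,
                              tremor_rho = 0, tremor_phase = 0,
                              wiggle_jitter = rep(0L, cfg$n_wiggles)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(retro_magnitude) || retro_magnitude < 0) {
    stop("invalid-argument: retro_magnitude must be finite and >= 0")
  }
  y <- .base_trace(cfg, peak_heights)
  c1 <- cfg$peak1_center; c2 <- cfg$peak2_center
  inner <- (c1 + 1):(c2 - 1)
  t0 <- inner[which.min(y[inner])]
  if (tremor_rho > 0) {
    y <- y + .flank_tremor(y, tremor_rho, tremor_phase, cfg$tremor_period)
    # guarantee a clean descend-then-ascend inter-peak profile
    y <- .enforce_monotone(y, c1:t0, -1)
    y <- .enforce_monotone(y, t0:c2, +1)
  }
  if (retro_magnitude > 0) {
    n_w <- cfg$n_wiggles
    r <- cfg$wiggle_halfwidth
    half <- ceiling(n_w / 2)
    contrib <- retro_magnitude / n_w
    slot <- 2 * r + 3
    for (k in seq_len(half)) {      # descending side, nearest trough first
      a <- t0 - 1 - 2 * r - (k - 1) * slot + wiggle_jitter[k]
      if (a <= c1 + 1) stop("invalid-config: no room for reversals")
      y <- .plant_tent(y, a, r, contrib, side = -1)
    }
    for (k in seq_len(n_w - half)) {  # ascending side
      a <- t0 + 1 + (k - 1) * slot + wiggle_jitter[half + k]
      if (a + 2 * r >= c2 - 1) stop("invalid-config: no room for reversals")
      y <- .plant_tent(y, a, r, contrib, side = +1)
    }
  }
  if (noise_sd > 0) y <- y + rnorm(cfg$trace_len, 0, noise_sd)
  y
}

# Gaussian truncated at zero (rejection sampling, vectorized redraw).
.rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(pmax(rep(mean, n), 0))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Gaussian truncated to [lo, hi].
.rtruncnorm_range <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lo), hi))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Draws per-eye covariates and peak heights, one clean trace per eye with a
#' planted retrogressive magnitude, `n_replicates` noisy measurements per eye
#' with per-measurement quality indices, and PRAA values from the planted
#' linear link. The same configuration and seed always produce a bit-identical
#' bundle.
#'
#' @param cfg A [sim_config()].
#'
#' @return An object of class `ora_cohort`: a list with
#'   \describe{
#'     \item{records}{a [waveform_set()] of all measurements}
#'     \item{covariates}{data.frame of per-eye covariates including PRAA}
#'     \item{truth}{planted ground truth: `retro` (per-eye magnitude),
#'       `clean_traces` (eyes x samples matrix), `praa_coefs`,
#'       `praa_intercept`, `support`, and the per-eye `predictors` used
#'       to build PRAA}
#'     \item{cfg}{the configuration}
#'   }
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_eyes < 2) stop("invalid-config: n_eyes must be >= 2")
  set.seed(cfg$seed)
  n <- cfg$n_eyes
  eye_id <- sprintf("eye%04d", seq_len(n))

  cm <- cfg$covariate_moments
  cov <- data.frame(eye_id = eye_id, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cm))) {
    cov[[cm$variable[k]]] <- rnorm(n, cm$mean[k], cm$sd[k])
  }
  cov$AL <- pmax(cov$AL, 0.1)  # axial length is physically positive

  h1 <- rnorm(n, cfg$peak1_height_mean, cfg$peak1_height_sd)
  h2 <- rnorm(n, cfg$peak2_height_mean, cfg$peak2_height_sd)
  retro <- .rtruncnorm_pos(n, cfg$retro_mean, cfg$retro_sd)
  tremor_rho <- pmin(abs(rnorm(n, 0, cfg$tremor_rho_sd)), cfg$tremor_cap)
  tremor_phase <- runif(n, 0, 2 * pi)

  clean <- matrix(NA_real_, n, cfg$trace_len)
  for (i in seq_len(n)) {
    jit <- sample(-1:1, cfg$n_wiggles, replace = TRUE)
    clean[i, ] <- simulate_waveform(cfg, retro[i],
                                    peak_heights = c(h1[i], h2[i]),
                                    noise_sd = 0,
                                    tremor_rho = tremor_rho[i],
                                    tremor_phase = tremor_phase[i],
                                    wiggle_jitter = jit)
  }

  nrec <- n * cfg$n_replicates
  traces <- clean[rep(seq_len(n), each = cfg$n_replicates), , drop = FALSE]
  if (cfg$noise_sd > 0) {
    traces <- traces + matrix(rnorm(length(traces), 0, cfg$noise_sd),
                              nrow = nrec)
  }
  qi <- .rtruncnorm_range(nrec, cfg$qi_mean, cfg$qi_sd, 0, 10)
  if (cfg$qi_low_fraction > 0) {
    n_low <- floor(cfg$qi_low_fraction * nrec)
    if (n_low > 0) {
      low_idx <- sample.int(nrec, n_low)
      qi[low_idx] <- runif(n_low, 6, 7.5)
    }
  }
  meta <- data.frame(
    eye_id = rep(eye_id, each = cfg$n_replicates),
    replicate_id = rep(seq_len(cfg$n_replicates), times = n),
    quality_index = qi,
    stringsAsFactors = FALSE
  )
  records <- waveform_set(meta, traces)

  # Predictor values for the planted PRAA link. The monot12 predictor is the
  # eye's true (noise-free) retrogressive magnitude; any other waveform
  # feature named in praa_coefs is computed from the clean trace.
  preds <- cov[setdiff(names(cov), "eye_id")]
  preds$monot12 <- retro
  extra <- setdiff(names(cfg$praa_coefs), names(preds))
  if (length(extra) > 0) {
    feats <- t(vapply(seq_len(n), function(i) {
      pk <- detect_applanation_peaks(clean[i, ])
      unlist(surrogate_descriptors(clean[i, ], pk))
    }, numeric(length(.SURROGATE_NAMES))))
    missing_names <- setdiff(extra, colnames(feats))
    if (length(missing_names) > 0) {
      stop("invalid-config: unknown predictors in praa_coefs: ",
           paste(missing_names, collapse = ", "))
    }
    for (nm in extra) preds[[nm]] <- feats[, nm]
  }
  lin <- cfg$praa_intercept +
    as.matrix(preds[names(cfg$praa_coefs)]) %*% cfg$praa_coefs
  cov$PRAA <- as.numeric(lin) + rnorm(n, 0, cfg$praa_noise_sd)

  truth <- list(
    retro = setNames(retro, eye_id),
    clean_traces = clean,
    peak_heights = cbind(h1 = h1, h2 = h2),
    tremor = cbind(rho = tremor_rho, phase = tremor_phase),
    praa_coefs = cfg$praa_coefs,
    praa_intercept = cfg$praa_intercept,
    support = names(cfg$praa_coefs)[cfg$praa_coefs != 0],
    predictors = preds
  )
  structure(list(records = records, covariates = cov, truth = truth,
                 cfg = cfg),
            class = "ora_cohort")
}

#' Names of predictors with nonzero planted PRAA coefficients
#'
#' @param truth The `truth` element of an `ora_cohort` (or a named coefficient
#'   vector).
#' @return Character vector of predictor names.
#' @export
planted_support <- function(truth) {
  coefs <- if (is.list(truth)) truth$praa_coefs else truth
  if (is.null(coefs)) stop("truth has no planted coefficients")
  names(coefs)[coefs != 0]
}

#' Write a simulator configuration as a flat key-value YAML file
#'
#' @param cfg A [sim_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  lst <- unclass(cfg)
  lst$covariate_moments <- as.list(cfg$covariate_moments)
  lst$praa_coefs <- as.list(cfg$praa_coefs)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a simulator configuration written by [write_sim_config()]
#'
#' @param path YAML path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$covariate_moments <- as.data.frame(lst$covariate_moments,
                                         stringsAsFactors = FALSE)
  lst$praa_coefs <- unlist(lst$praa_coefs)
  do.call(sim_config, lst)
}

#' @export
print.ora_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic ORA cohort: %d eyes x %d replicates (%d records, %d samples)\n",
    x$cfg$n_eyes, x$cfg$n_replicates, nrow(x$records$meta),
    x$cfg$trace_len))
  cat("Planted PRAA support:",
      paste(planted_support(x$truth), collapse = ", "), "\n")
  invisible(x)
}
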
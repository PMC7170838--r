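# Applanation-peak detection, the Monot1-2 retrogressive-movement statistic,
# and a documented surrogate set of classical ORA waveform descriptors.
# The surrogate definitions are this package's own (the vendor's algorithms
# are unpublished); numerical agreement with the ORA software is not claimed.

# Canonical descriptor order: the 37 classical parameters, then monot12.
.SURROGATE_NAMES <- c(
  "Aindex", "Bindex", "p1area", "p2area", "aspect1", "aspect2",
  "uslope1", "uslope2", "dslope1", "dslope2", "w1", "w2", "h1", "h2",
  "dive1", "dive2", "path1", "path2", "mslew1", "mslew2", "slew1", "slew2",
  "Aplhf", "p1area1", "p2area1", "aspect11", "aspect21",
  "uslope11", "uslope21", "dslope11", "dslope21", "w11", "w21",
  "h11", "h21", "path11", "path21"
)
.FEATURE_NAMES <- c(.SURROGATE_NAMES, "monot12")

# Centered moving average; edges keep the raw values (window shrinks is not
# needed for interior peaks).
.moving_avg <- function(y, window) {
  sm <- as.numeric(stats::filter(y, rep(1 / window, window), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  sm
}

# Indices of local maxima (strictly above the previous sample, at or above
# the next, so the left edge of a plateau counts once).
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
}

# Topographic prominence of a peak: height above the higher of the two key
# saddles (minimum on each side before reaching higher ground or a boundary).
.prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    higher <- which(left > h)
    lmin <- if (length(higher) > 0) min(left[(max(higher)):(p - 1)]) else min(left)
    right <- y[(p + 1):length(y)]
    higher <- which(right > h)
    rmin <- if (length(higher) > 0) min(right[seq_len(min(higher))]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect the two applanation peaks and the inter-peak trough
#'
#' The trace is smoothed with a centered moving average (window 9 by
#' default); the two local maxima with highest topographic prominence that
#' are at least `min_separation` samples apart are taken as the applanation
#' peaks. Each smoothed peak is snapped to the nearest raw local maximum
#' within `snap` samples (falling back to the raw argmax of that window).
#' The trough is the earliest global minimum of the raw trace strictly
#' between the peaks.
#'
#' @param trace Numeric waveform vector.
#' @param window Smoothing window, samples.
#' @param min_separation Minimum peak separation, samples.
#' @param snap Half-width for snapping smoothed peaks to the raw trace.
#' @return Object of class `peak_pair`: list with `p1`, `trough`, `p2`.
#' @export
detect_applanation_peaks <- function(trace, window = 9, min_separation = 40,
                                     snap = 5) {
  if (length(trace) < window + 2) {
    stop("invalid-argument: trace shorter than smoothing window")
  }
  if (any(!is.finite(trace))) stop("invalid-argument: non-finite samples")
  sm <- .moving_avg(trace, window)
  cand <- .local_maxima(sm)
  if (length(cand) < 2) stop("no-peaks: fewer than two local maxima")
  prom <- .prominence(sm, cand)
  ord <- cand[order(-prom)]
  first <- ord[1]
  second <- ord[which(abs(ord - first) >= min_separation)[1]]
  if (is.na(second)) {
    stop("no-peaks: no second maximum at least ", min_separation,
         " samples away")
  }
  # refine each smoothed peak by the vertex of a local quadratic fit
  # (sub-sample localization is far less noise-sensitive than the argmax)
  refine <- function(p) {
    lo <- max(1, p - window); hi <- min(length(sm), p + window)
    xs <- (lo:hi) - p
    b <- .lm.fit(cbind(1, xs, xs^2), sm[lo:hi])$coefficients
    if (is.finite(b[3]) && b[3] < 0) {
      v <- -b[2] / (2 * b[3])
      if (abs(v) <= window) return(p + round(v))
    }
    p
  }
  snap_raw <- function(p) {
    lo <- max(2, p - snap); hi <- min(length(trace) - 1, p + snap)
    win <- lo:hi
    locmax <- win[trace[win] > trace[win - 1] & trace[win] >= trace[win + 1]]
    if (length(locmax) > 0) locmax[which.min(abs(locmax - p))]
    else win[which.max(trace[win])]
  }
  pk <- sort(c(snap_raw(refine(first)), snap_raw(refine(second))))
  p1 <- pk[1]; p2 <- pk[2]
  inner <- (p1 + 1):(p2 - 1)
  trough <- inner[which.min(trace[inner])]
  structure(list(p1 = p1, trough = trough, p2 = p2), class = "peak_pair")
}

.check_peaks <- function(trace, peaks) {
  if (!all(c("p1", "trough", "p2") %in% names(peaks))) {
    stop("invalid-argument: peaks must have p1, trough, p2")
  }
  with(peaks, {
    if (!(p1 < trough && trough < p2)) {
      stop("invalid-argument: need p1 < trough < p2")
    }
    if (p1 < 1 || p2 > length(trace)) {
      stop("invalid-argument: peak indices outside trace")
    }
  })
  invisible(TRUE)
}

#' Monot1-2: total retrogressive movement between the applanation peaks
#'
#' The inter-peak segment of a clean applanation waveform descends
#' monotonically from peak 1 to the trough and ascends monotonically from the
#' trough to peak 2. Monot1-2 totals the movement *against* that profile:
#' upward steps before the trough plus downward steps after it,
#' `sum(max(0, y[i+1]-y[i]))` for `i` in `p1..trough-1` plus
#' `sum(max(0, y[i]-y[i+1]))` for `i` in `trough..p2-1`. It is zero exactly
#' when the segment is non-increasing before the trough and non-decreasing
#' after it, translation-invariant, and positively homogeneous of degree 1.
#'
#' The `"arclength"` method instead totals the path length of the adverse
#' steps, `sum(sqrt(1 + dy^2))` over the same steps.
#'
#' @param trace Numeric waveform vector.
#' @param peaks A `peak_pair` (from [detect_applanation_peaks()]) or a list
#'   with `p1`, `trough`, `p2`.
#' @param method `"adverse"` (default) or `"arclength"`.
#' @return Non-negative scalar, signal units.
#' @export
monot12 <- function(trace, peaks, method = c("adverse", "arclength")) {
  method <- match.arg(method)
  .check_peaks(trace, peaks)
  d1 <- diff(trace[peaks$p1:peaks$trough])
  d2 <- diff(trace[peaks$trough:peaks$p2])
  adverse <- c(d1[d1 > 0], -d2[d2 < 0])
  switch(method,
         adverse = sum(adverse),
         arclength = if (length(adverse) == 0) 0
                     else sum(sqrt(1 + adverse^2)))
}

# Fractional crossing position of level L on the flank of a peak.
# side = -1: walk left from p (rising flank); side = +1: walk right (falling).
# Returns the interpolated x where the trace crosses L, or the region
# boundary if the trace never drops below L on that side.
.crossing <- function(y, p, L, bound, side) {
  i <- p
  while (i != bound && y[i + side] >= L) i <- i + side
  if (i == bound) return(as.numeric(bound))
  j <- i + side  # first sample below L
  # linear interpolation between j (below L) and i (at or above L)
  frac <- (L - y[j]) / (y[i] - y[j])
  j + frac * (i - j)
}

# Integral of (y(x) - L) over [xl, xr], y piecewise linear between samples.
.area_above <- function(y, xl, xr, L) {
  if (xr <= xl) return(0)
  grid <- seq(ceiling(xl), floor(xr))
  xs <- unique(c(xl, grid, xr))
  ys <- approx(seq_along(y), y, xout = xs)$y
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2) - L * (xr - xl)
}

# Descriptors of one peak at one height cut.
.peak_cut_features <- function(y, p, base, h, f, lo, hi) {
  L <- base + f * h
  xl <- .crossing(y, p, L, lo, -1L)
  xr <- .crossing(y, p, L, hi, +1L)
  w <- max(xr - xl, 1)
  idx <- seq(ceiling(xl), floor(xr))
  list(w = w,
       area = max(.area_above(y, xl, xr, L), 0),
       path = sum(y[idx] > L),
       xl = xl, xr = xr)
}

# Mean slope between two levels on one flank.
.flank_slope <- function(y, p, base, h, f_lo, f_hi, lo, hi, side) {
  L1 <- base + f_lo * h
  L2 <- base + f_hi * h
  x1 <- .crossing(y, p, L1, if (side < 0) lo else hi, side)
  x2 <- .crossing(y, p, L2, if (side < 0) lo else hi, side)
  dx <- abs(x1 - x2)
  if (dx < 1e-9) dx <- 1e-9
  (L2 - L1) / dx
}

#' Surrogate classical waveform descriptors
#'
#' Computes this package's operational definitions of the classical ORA
#' waveform parameters (the vendor's algorithms are unpublished; these are
#' documented surrogates, not reproductions):
#' baseline = median of the first `baseline_n` samples; `h` = peak height
#' above baseline; `dive` = peak height above the inter-peak trough;
#' `w` = width at 75% of peak height (interpolated crossings);
#' `area` = area above the 75% cut; `uslope`/`dslope` = mean slope of the
#' rising/falling flank between the 25% and 75% levels;
#' `aspect` = `h/w * 10`; `path` = number of samples above the 75% cut;
#' `slew` = maximum single-step rise on the rising flank; `mslew` = maximum
#' rise over any 3-step run; `Aindex`/`Bindex` = `10 - min(10, n)` where `n`
#' counts adverse steps on the flanks of peak 1/peak 2;
#' `Aplhf` = 10 x high-frequency residual power ratio (trace minus its
#' window-`smooth_window` moving average, inter-peak region).
#' The `"1"`-suffixed variants replace the 75% cut with 50% (slope bands
#' become 25%-50%); `h11`/`h21` are the peak heights above the 50% cut and
#' hence exactly proportional to `h1`/`h2`.
#'
#' @param trace Numeric waveform vector.
#' @param peaks A `peak_pair` for this trace.
#' @param smooth_window Window for the high-frequency residual (default 9).
#' @param baseline_n Number of leading samples defining the baseline.
#' @return Named list with all descriptor fields except `monot12`.
#' @export
surrogate_descriptors <- function(trace, peaks, smooth_window = 9,
                                  baseline_n = 50) {
  .check_peaks(trace, peaks)
  y <- unname(as.numeric(trace))
  n <- length(y)
  p1 <- peaks$p1; p2 <- peaks$p2; tr <- peaks$trough
  base <- median(y[seq_len(min(baseline_n, n))])
  h1 <- y[p1] - base
  h2 <- y[p2] - base
  if (h1 <= 0) stop("feature error: h1 not above baseline")
  if (h2 <= 0) stop("feature error: h2 not above baseline")

  out <- list()
  out$h1 <- h1; out$h2 <- h2
  out$dive1 <- y[p1] - y[tr]
  out$dive2 <- y[p2] - y[tr]

  # peak regions: peak 1 owns [1, trough], peak 2 owns [trough, n]
  reg <- list(list(p = p1, h = h1, lo = 1L, hi = tr),
              list(p = p2, h = h2, lo = tr, hi = n))
  for (k in 1:2) {
    r <- reg[[k]]
    main <- .peak_cut_features(y, r$p, base, r$h, 0.75, r$lo, r$hi)
    alt <- .peak_cut_features(y, r$p, base, r$h, 0.50, r$lo, r$hi)
    out[[paste0("w", k)]] <- main$w
    out[[paste0("w", k, "1")]] <- alt$w
    out[[paste0("p", k, "area")]] <- main$area
    out[[paste0("p", k, "area1")]] <- alt$area
    out[[paste0("path", k)]] <- main$path
    out[[paste0("path", k, "1")]] <- alt$path
    out[[paste0("aspect", k)]] <- r$h / main$w * 10
    out[[paste0("aspect", k, "1")]] <- r$h / alt$w * 10
    out[[paste0("uslope", k)]] <-
      .flank_slope(y, r$p, base, r$h, 0.25, 0.75, r$lo, r$hi, -1L)
    out[[paste0("uslope", k, "1")]] <-
      .flank_slope(y, r$p, base, r$h, 0.25, 0.50, r$lo, r$hi, -1L)
    out[[paste0("dslope", k)]] <-
      abs(.flank_slope(y, r$p, base, r$h, 0.25, 0.75, r$lo, r$hi, +1L))
    out[[paste0("dslope", k, "1")]] <-
      abs(.flank_slope(y, r$p, base, r$h, 0.25, 0.50, r$lo, r$hi, +1L))
    # slew: rising flank from the 25% crossing up to the peak
    x25 <- .crossing(y, r$p, base + 0.25 * r$h, r$lo, -1L)
    a <- max(r$lo, floor(x25))
    d <- diff(y[a:r$p])
    out[[paste0("slew", k)]] <- if (length(d) > 0) max(d) else 0
    out[[paste0("mslew", k)]] <-
      if (r$p - a >= 3) max(y[(a + 3):r$p] - y[a:(r$p - 3)])
      else out[[paste0("slew", k)]]
    # adverse steps on both flanks (within the 25% cut)
    xr25 <- .crossing(y, r$p, base + 0.25 * r$h, r$hi, +1L)
    b <- min(r$hi, ceiling(xr25))
    n_adv <- sum(diff(y[a:r$p]) < 0) + sum(diff(y[r$p:b]) > 0)
    out[[if (k == 1) "Aindex" else "Bindex"]] <- 10 - min(10, n_adv)
  }
  out$h11 <- 0.5 * h1
  out$h21 <- 0.5 * h2

  seg <- p1:p2
  res <- y[seg] - .moving_avg(y, smooth_window)[seg]
  denom <- sum((y[seg] - mean(y[seg]))^2)
  out$Aplhf <- if (denom > 0) 10 * sum(res^2) / denom else 0

  out[.SURROGATE_NAMES]
}

#' Full feature table for a set of waveforms
#'
#' Detects peaks and computes [surrogate_descriptors()] and [monot12()] for
#' every measurement in a waveform set (typically one averaged record per
#' eye).
#'
#' @param ws A [waveform_set()] or a traces matrix.
#' @param eye_id Eye identifiers when `ws` is a bare matrix.
#' @param monot_method Passed to [monot12()].
#' @return data.frame with `eye_id` and one column per feature.
#' @export
feature_table <- function(ws, eye_id = NULL,
                          monot_method = c("adverse", "arclength")) {
  monot_method <- match.arg(monot_method)
  if (inherits(ws, "waveform_set")) {
    traces <- ws$traces
    eye_id <- ws$meta$eye_id
  } else {
    traces <- as.matrix(ws)
    if (is.null(eye_id)) eye_id <- sprintf("eye%04d", seq_len(nrow(traces)))
  }
  rows <- lapply(seq_len(nrow(traces)), function(i) {
    y <- unname(as.numeric(traces[i, ]))
    pk <- detect_applanation_peaks(y)
    f <- surrogate_descriptors(y, pk)
    f$monot12 <- monot12(y, pk, method = monot_method)
    unlist(f)[.FEATURE_NAMES]
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(eye_id = eye_id, stringsAsFactors = FALSE), out)
}

#' Assemble the regression design for PRAA
#'
#' Joins per-eye waveform features with covariates into the predictor matrix:
#' age, AL, SERE, CH, CRF, the 35 surrogate descriptors (`h11` and `h21` are
#' excluded as exactly proportional to `h1`/`h2`), and `monot12` -- 41
#' columns in total. The response is PRAA. Keratometry is measured and kept
#' in the covariate table but enters the design only on request (the
#' published variable list keeps it out of the regression).
#'
#' @param features data.frame from [feature_table()].
#' @param covariates data.frame with `eye_id`, the covariates and `PRAA`.
#' @param exclude Feature columns dropped for collinearity
#'   (default `h11`, `h21`).
#' @param include_keratometry Add keratometry as a 42nd predictor column.
#' @return List with `X` (raw predictor matrix), `X_std` (standardized copy),
#'   `y` (PRAA), `eye_id`.
#' @export
assemble_design_matrix <- function(features, covariates,
                                   exclude = c("h11", "h21"),
                                   include_keratometry = FALSE) {
  stopifnot(is.data.frame(features), is.data.frame(covariates))
  cov_names <- c("age", "AL", "SERE", "CH", "CRF")
  if (include_keratometry) cov_names <- c(cov_names, "keratometry")
  need <- c("eye_id", cov_names, "PRAA")
  if (!all(need %in% names(covariates))) {
    stop("assembly error: covariates must contain ",
         paste(setdiff(need, names(covariates)), collapse = ", "))
  }
  missing_eyes <- setdiff(features$eye_id, covariates$eye_id)
  if (length(missing_eyes) > 0) {
    stop("assembly error: eye(s) missing covariates: ",
         paste(missing_eyes, collapse = ", "))
  }
  cov <- covariates[match(features$eye_id, covariates$eye_id), ]
  bad_praa <- features$eye_id[!is.finite(cov$PRAA)]
  if (length(bad_praa) > 0) {
    stop("assembly error: eye(s) missing PRAA: ",
         paste(bad_praa, collapse = ", "))
  }
  feat_cols <- setdiff(.FEATURE_NAMES, exclude)
  X <- cbind(as.matrix(cov[cov_names]), as.matrix(features[feat_cols]))
  rownames(X) <- features$eye_id
  list(X = X, X_std = scale(X), y = cov$PRAA, eye_id = features$eye_id)
}
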
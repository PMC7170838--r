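# Two-step predictor selection for PRAA: Lasso screening to a fixed number
# of candidates, then exhaustive best-subset search under the second-order
# bias-corrected Akaike information criterion (AICc), plus a univariate scan
# and nested-model ANOVA comparison.

#' Second-order bias-corrected Akaike information criterion
#'
#' For a Gaussian linear model with `n_slopes` slope coefficients fitted by
#' least squares, with `p = n_slopes + 2` counted parameters (slopes,
#' intercept, and residual variance):
#' `AICc = n*log(2*pi*rss/n) + n + 2p + 2p(p+1)/(n - p - 1)`.
#' This is the Gaussian log-likelihood convention used by `stats::AIC()`, so
#' AICc differences agree with nested log-likelihood comparisons.
#'
#' @param n Number of observations.
#' @param rss Residual sum of squares (> 0).
#' @param n_slopes Number of slope coefficients.
#' @return Scalar AICc.
#' @export
aicc <- function(n, rss, n_slopes) {
  if (!is.finite(rss) || rss <= 0) stop("degenerate-fit error: rss must be > 0")
  p <- n_slopes + 2
  if (n - p - 1 < 1) {
    stop("saturation error: n - p - 1 must be >= 1 (n = ", n, ", p = ", p, ")")
  }
  n * log(2 * pi * rss / n) + n + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Screen predictors with the Lasso
#'
#' Computes the L1 regularization path (columns standardized) and picks the
#' largest penalty at which at least `k` coefficients are nonzero; the `k`
#' features with largest absolute standardized coefficient at that penalty
#' are returned. Ties are broken by earlier entry along the path, then by
#' column order, so exactly `k` names are always returned.
#'
#' @param X Predictor matrix with column names.
#' @param y Response vector.
#' @param k Number of candidates (default 20).
#' @return Character vector of `k` column names.
#' @export
lasso_screen <- function(X, y, k = 20) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("dropping constant column(s) before screening: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  if (k > ncol(X)) {
    stop("invalid-argument: k (", k, ") exceeds usable columns (", ncol(X), ")")
  }
  if (k == ncol(X)) return(colnames(X))
  fit <- glmnet::glmnet(X, y, alpha = 1, standardize = TRUE,
                        nlambda = 200, lambda.min.ratio = 1e-4)
  beta <- as.matrix(fit$beta)
  nz_count <- colSums(beta != 0)
  sel <- which(nz_count >= k)[1]
  if (is.na(sel)) sel <- ncol(beta)  # path never reached k: use the end
  std_coef <- abs(beta[, sel]) * sds
  entry <- apply(beta != 0, 1, function(r) {
    w <- which(r)
    if (length(w) > 0) w[1] else Inf
  })
  ord <- order(-std_coef, entry, seq_along(std_coef))
  colnames(X)[ord[seq_len(k)]]
}

# OLS fit record for a named subset (refit on raw columns).
.ols_fit <- function(X, y, subset) {
  n <- length(y)
  df <- as.data.frame(X[, subset, drop = FALSE])
  df$.y <- y
  fit <- if (length(subset) == 0) lm(.y ~ 1, data = df)
         else lm(.y ~ ., data = df)
  sm <- summary(fit)
  ct <- sm$coefficients
  rss <- sum(residuals(fit)^2)
  structure(list(
    subset = subset,
    coefficients = data.frame(term = rownames(ct),
                              estimate = ct[, 1], std_error = ct[, 2],
                              p_value = ct[, 4],
                              row.names = NULL,
                              stringsAsFactors = FALSE),
    rss = rss,
    loglik = -n / 2 * (log(2 * pi * rss / n) + 1),
    aicc = aicc(n, rss, length(subset)),
    n = n,
    lm = fit
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %s (n = %d)\n",
              if (length(x$subset) == 0) "intercept only"
              else paste(x$subset, collapse = " + "), x$n))
  print(x$coefficients, digits = 4)
  cat(sprintf("RSS = %.4g, logLik = %.4g, AICc = %.4g\n",
              x$rss, x$loglik, x$aicc))
  invisible(x)
}

.mask_to_names <- function(mask, candidates) {
  bits <- which(bitwAnd(rep(mask, length(candidates)),
                        2^(seq_along(candidates) - 1)) != 0)
  candidates[bits]
}

#' Exhaustive best-subset search under AICc
#'
#' Evaluates all `2^k` subsets of the candidate predictors (including the
#' intercept-only model) by Gray-code sweep updates of the centered
#' cross-product matrix, and refits the minimum-AICc subset by ordinary least
#' squares on the raw columns for coefficients, standard errors and p-values.
#' Subsets too large for the sample size (`n - p - 1 < 1`) are skipped and
#' counted. Candidate columns that are linearly dependent are dropped with a
#' warning before the search (a subset of linearly independent columns is
#' always full-rank).
#'
#' @param X Predictor matrix with column names.
#' @param y Response vector.
#' @param candidates Candidate column names (at most 24).
#' @param top_k Number of leaderboard entries to keep (default 10).
#' @param return_all Also return the AICc of every subset (indexed by the
#'   subset's bitmask over `candidates`); intended for small candidate sets.
#' @return Object of class `selection_result`: `candidates`, `best`
#'   (an `ols_fit`), `aicc_table`, `n_models_evaluated`, `n_skipped`, and
#'   (with `return_all`) `all_aicc`.
#' @export
exhaustive_aicc_search <- function(X, y, candidates, top_k = 10,
                                   return_all = FALSE) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (length(candidates) > 24) {
    stop("invalid-argument: at most 24 candidates are tractable (2^24 subsets)")
  }
  missing_cols <- setdiff(candidates, colnames(X))
  if (length(missing_cols) > 0) {
    stop("unknown candidate column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(candidates) == 0) {
    best <- .ols_fit(X, y, character(0))
    return(structure(list(candidates = character(0), best = best,
                          aicc_table = data.frame(subset = "(intercept)",
                                                  size = 0, rss = best$rss,
                                                  aicc = best$aicc),
                          n_models_evaluated = 1, n_skipped = 0),
                     class = "selection_result"))
  }
  Xc <- scale(X[, candidates, drop = FALSE])
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    dep <- candidates[-qrx$pivot[seq_len(qrx$rank)]]
    warning("dropping linearly dependent candidate(s): ",
            paste(dep, collapse = ", "))
    candidates <- setdiff(candidates, dep)
    Xc <- scale(X[, candidates, drop = FALSE])
  }
  yc <- y - mean(y)
  M <- crossprod(cbind(Xc, yc))
  res <- gray_sweep_search(M, n, as.integer(top_k), return_all)

  best_names <- .mask_to_names(res$best_mask, candidates)
  best <- .ols_fit(X, y, best_names)

  keep <- is.finite(res$top_aicc)
  tab <- data.frame(
    subset = vapply(res$top_mask[keep], function(mk) {
      nm <- .mask_to_names(mk, candidates)
      if (length(nm) == 0) "(intercept)" else paste(nm, collapse = " + ")
    }, character(1)),
    size = vapply(res$top_mask[keep], function(mk) {
      length(.mask_to_names(mk, candidates))
    }, numeric(1)),
    rss = res$top_rss[keep],
    aicc = res$top_aicc[keep],
    stringsAsFactors = FALSE
  )
  structure(list(candidates = candidates, best = best, aicc_table = tab,
                 n_models_evaluated = res$n_evaluated,
                 n_skipped = res$n_skipped,
                 all_aicc = if (return_all) res$all_aicc else NULL),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Exhaustive AICc search over %d candidates (%s models)\n",
              length(x$candidates),
              format(x$n_models_evaluated, big.mark = ",")))
  print(x$best)
  invisible(x)
}

#' Univariate regression scan
#'
#' One simple linear regression of the response on each column; reports
#' coefficient, standard error, p-value and AICc per predictor. Constant
#' columns are flagged with `NA` and not fitted.
#'
#' @param X Predictor matrix with column names.
#' @param y Response vector.
#' @return data.frame with one row per column.
#' @export
univariate_scan <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  rows <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (sd(x) == 0 || !all(is.finite(x))) {
      return(data.frame(variable = colnames(X)[j], coefficient = NA_real_,
                        std_error = NA_real_, p_value = NA_real_,
                        aicc = NA_real_, constant = TRUE))
    }
    fit <- lm(y ~ x)
    ct <- summary(fit)$coefficients
    rss <- sum(residuals(fit)^2)
    data.frame(variable = colnames(X)[j], coefficient = ct[2, 1],
               std_error = ct[2, 2], p_value = ct[2, 4],
               aicc = aicc(n, rss, 1), constant = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nested-model comparison (ANOVA F-test)
#'
#' Compares two ordinary-least-squares fits of the same response where the
#' smaller model's predictors are a strict subset of the larger model's:
#' `F = [(RSS_small - RSS_large)/df_diff] / [RSS_large/(n - p_large - 1)]`,
#' with the p-value from the F distribution.
#'
#' @param small,large `ols_fit` objects (e.g. from
#'   [exhaustive_aicc_search()]`$best` or [refit_subset()]).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_nested <- function(small, large) {
  stopifnot(inherits(small, "ols_fit"), inherits(large, "ols_fit"))
  if (small$n != large$n) stop("invalid-argument: models fit on different n")
  if (!all(small$subset %in% large$subset) ||
      length(small$subset) >= length(large$subset)) {
    stop("invalid-argument: small model must be strictly nested in large")
  }
  df1 <- length(large$subset) - length(small$subset)
  df2 <- large$n - length(large$subset) - 1
  if (df2 < 1) stop("invalid-argument: large model has no residual df")
  Fstat <- ((small$rss - large$rss) / df1) / (large$rss / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Refit a named subset by ordinary least squares
#'
#' @param X Predictor matrix with column names.
#' @param y Response vector.
#' @param subset Character vector of column names (empty for intercept-only).
#' @return An `ols_fit`.
#' @export
refit_subset <- function(X, y, subset) {
  X <- as.matrix(X)
  missing_cols <- setdiff(subset, colnames(X))
  if (length(missing_cols) > 0) {
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  }
  .ols_fit(X, y, subset)
}

#' Serialize a selection result to JSON (plus a CSV leaderboard)
#'
#' @param sel A `selection_result`.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV path for the AICc leaderboard.
#' @return `json_path`, invisibly.
#' @export
write_selection_result <- function(sel, json_path, csv_path = NULL) {
  stopifnot(inherits(sel, "selection_result"))
  payload <- list(
    candidates = sel$candidates,
    best_subset = sel$best$subset,
    coefficients = sel$best$coefficients,
    rss = sel$best$rss,
    aicc = sel$best$aicc,
    n = sel$best$n,
    n_models_evaluated = sel$n_models_evaluated,
    n_skipped = sel$n_skipped
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    write.csv(sel$aicc_table, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
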
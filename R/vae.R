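# A small variational autoencoder for 400-sample applanation waveforms:
# encoder 400 -> 40 -> 20 -> (2 means + 2 log-variances), decoder mirrored
# (2 -> 20 -> 40 -> 400), ReLU hidden units, linear outputs, diagonal
# Gaussian posterior, Gaussian (mean-squared-error) reconstruction loss.
# Implemented in base R matrix code with hand-derived gradients and Adam;
# gradients are verified against finite differences in the test suite.

#' VAE architecture description
#'
#' @param input_dim Trace length (default 400).
#' @param encoder_hidden Encoder hidden widths (default `c(40, 20)`); the
#'   decoder mirrors them.
#' @param latent_dim Latent dimension (default 2).
#' @return Object of class `vae_arch`.
#' @export
vae_arch <- function(input_dim = 400, encoder_hidden = c(40, 20),
                     latent_dim = 2) {
  if (latent_dim < 1) stop("config error: latent_dim must be >= 1")
  if (input_dim < 1) stop("config error: input_dim must be >= 1")
  structure(list(input_dim = as.integer(input_dim),
                 encoder_hidden = as.integer(encoder_hidden),
                 latent_dim = as.integer(latent_dim),
                 decoder_hidden = rev(as.integer(encoder_hidden))),
            class = "vae_arch")
}

# Parameter names and shapes, in a fixed order.
.vae_layer_dims <- function(arch) {
  enc <- c(arch$input_dim, arch$encoder_hidden)
  dec <- c(arch$latent_dim, arch$decoder_hidden, arch$input_dim)
  dims <- list()
  for (i in seq_len(length(enc) - 1)) {
    dims[[paste0("enc", i, "_W")]] <- c(enc[i], enc[i + 1])
    dims[[paste0("enc", i, "_b")]] <- c(1, enc[i + 1])
  }
  k <- enc[length(enc)]
  dims$mu_W <- c(k, arch$latent_dim); dims$mu_b <- c(1, arch$latent_dim)
  dims$lv_W <- c(k, arch$latent_dim); dims$lv_b <- c(1, arch$latent_dim)
  for (i in seq_len(length(dec) - 1)) {
    dims[[paste0("dec", i, "_W")]] <- c(dec[i], dec[i + 1])
    dims[[paste0("dec", i, "_b")]] <- c(1, dec[i + 1])
  }
  dims
}

#' Number of trainable parameters of a VAE architecture
#' @param arch A [vae_arch()].
#' @return Integer parameter count (weights + biases).
#' @export
vae_n_params <- function(arch) {
  sum(vapply(.vae_layer_dims(arch), prod, numeric(1)))
}

#' Initialize a VAE model
#'
#' He-scaled Gaussian weights, zero biases; reproducible for a given seed.
#'
#' @param arch A [vae_arch()].
#' @param seed Integer seed.
#' @return Object of class `vae_model` with untrained weights.
#' @export
init_vae <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "vae_arch"))
  set.seed(seed)
  dims <- .vae_layer_dims(arch)
  params <- lapply(names(dims), function(nm) {
    d <- dims[[nm]]
    if (grepl("_b$", nm)) matrix(0, d[1], d[2])
    else matrix(rnorm(prod(d), 0, sqrt(2 / d[1])), d[1], d[2])
  })
  names(params) <- names(dims)
  structure(list(arch = arch, params = params, norm_const = NULL,
                 history = data.frame(), train_mu = NULL, seed = seed),
            class = "vae_model")
}

.relu <- function(x) (x > 0) * x

.add_bias <- function(X, b) sweep(X, 2, as.numeric(b), "+")

# Forward pass through the encoder; keeps hidden activations for backprop.
.vae_encode_full <- function(model, X) {
  n_enc <- length(model$arch$encoder_hidden)
  A <- list(X)
  for (i in seq_len(n_enc)) {
    Z <- .add_bias(A[[i]] %*% model$params[[paste0("enc", i, "_W")]],
                   model$params[[paste0("enc", i, "_b")]])
    A[[i + 1]] <- .relu(Z)
  }
  H <- A[[n_enc + 1]]
  list(A = A,
       mu = .add_bias(H %*% model$params$mu_W, model$params$mu_b),
       lv = .add_bias(H %*% model$params$lv_W, model$params$lv_b))
}

.vae_decode_full <- function(model, Z) {
  n_dec <- length(model$arch$decoder_hidden)
  B <- list(Z)
  for (i in seq_len(n_dec)) {
    Zi <- .add_bias(B[[i]] %*% model$params[[paste0("dec", i, "_W")]],
                    model$params[[paste0("dec", i, "_b")]])
    B[[i + 1]] <- .relu(Zi)
  }
  i <- n_dec + 1
  out <- .add_bias(B[[n_dec + 1]] %*% model$params[[paste0("dec", i, "_W")]],
                   model$params[[paste0("dec", i, "_b")]])
  list(B = B, out = out)
}

#' Encode traces to latent codes
#'
#' @param model A `vae_model`.
#' @param traces Vector (one trace) or matrix (one trace per row), raw
#'   signal units; normalized internally by the model's constant.
#' @return List with `mu` and `logvar` matrices (one row per trace).
#' @export
vae_encode <- function(model, traces) {
  X <- .as_trace_matrix(traces, model$arch$input_dim)
  nc <- .norm_const_of(model, X)
  enc <- .vae_encode_full(model, X / nc)
  list(mu = enc$mu, logvar = enc$lv)
}

#' Decode latent codes to traces
#'
#' @param model A `vae_model`.
#' @param z Latent vector or matrix (one code per row).
#' @return Matrix of decoded traces in raw signal units.
#' @export
vae_decode <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  nc <- if (is.null(model$norm_const)) 1 else model$norm_const
  .vae_decode_full(model, z)$out * nc
}

.as_trace_matrix <- function(traces, input_dim) {
  X <- if (is.null(dim(traces))) matrix(traces, nrow = 1) else as.matrix(traces)
  if (ncol(X) != input_dim) {
    stop("config error: trace length ", ncol(X),
         " does not match encoder input dimension ", input_dim)
  }
  X
}

.norm_const_of <- function(model, X) {
  if (!is.null(model$norm_const)) return(model$norm_const)
  warning("model is untrained (no normalization constant); using max |value|")
  m <- max(abs(X))
  if (m == 0) 1 else m
}

#' Kullback-Leibler divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `0.5 * sum(exp(logvar) + mu^2 - 1 - logvar)` over latent
#' dimensions; non-negative, zero exactly at `mu = 0`, `logvar = 0`.
#'
#' @param code List with `mu` and `logvar` (vectors, or matrices with one
#'   code per row).
#' @return Scalar KL (or vector, one per row for matrix input).
#' @export
kl_standard_normal <- function(code) {
  mu <- code$mu; lv <- code$logvar
  if (any(!is.finite(mu)) || any(!is.finite(lv))) {
    stop("invalid-argument: non-finite latent code")
  }
  if (is.null(dim(mu))) {
    0.5 * sum(exp(lv) + mu^2 - 1 - lv)
  } else {
    0.5 * rowSums(exp(lv) + mu^2 - 1 - lv)
  }
}

#' Evidence-lower-bound loss of a batch
#'
#' Reconstruction term: mean over the batch of the squared error summed over
#' observation points (Gaussian decoder, unit variance), evaluated at the
#' posterior mean. KL term: mean over the batch of [kl_standard_normal()].
#' Total = reconstruction + beta * KL.
#'
#' @param traces Batch of traces (vector or matrix), raw signal units.
#' @param model A `vae_model`.
#' @param beta KL weight (default 1).
#' @return List with `reconstruction`, `kl`, `total`.
#' @export
elbo_loss <- function(traces, model, beta = 1) {
  X <- .as_trace_matrix(traces, model$arch$input_dim)
  nc <- .norm_const_of(model, X)
  Xn <- X / nc
  if (max(abs(Xn)) > 10) {
    warning("input far outside the normalized training range (|value| > 10)")
  }
  enc <- .vae_encode_full(model, Xn)
  out <- .vae_decode_full(model, enc$mu)$out
  recon <- mean(rowSums((Xn - out)^2))
  kl <- mean(kl_standard_normal(list(mu = enc$mu, logvar = enc$lv)))
  list(reconstruction = recon, kl = kl, total = recon + beta * kl)
}

# Loss and gradients of one sampled minibatch (normalized input).
.vae_grad <- function(model, Xn, eps, beta) {
  n_enc <- length(model$arch$encoder_hidden)
  n_dec <- length(model$arch$decoder_hidden)
  P <- model$params
  B <- nrow(Xn)

  enc <- .vae_encode_full(model, Xn)
  mu <- enc$mu; lv <- enc$lv
  z <- mu + exp(lv / 2) * eps
  dec <- .vae_decode_full(model, z)
  out <- dec$out

  recon <- mean(rowSums((Xn - out)^2))
  kl <- mean(kl_standard_normal(list(mu = mu, logvar = lv)))
  loss <- recon + beta * kl

  g <- list()
  dout <- (2 / B) * (out - Xn)
  i <- n_dec + 1
  g[[paste0("dec", i, "_W")]] <- crossprod(dec$B[[n_dec + 1]], dout)
  g[[paste0("dec", i, "_b")]] <- matrix(colSums(dout), 1)
  dA <- dout %*% t(P[[paste0("dec", i, "_W")]])
  for (i in rev(seq_len(n_dec))) {
    dZ <- dA * (dec$B[[i + 1]] > 0)
    g[[paste0("dec", i, "_W")]] <- crossprod(dec$B[[i]], dZ)
    g[[paste0("dec", i, "_b")]] <- matrix(colSums(dZ), 1)
    dA <- dZ %*% t(P[[paste0("dec", i, "_W")]])
  }
  dz <- dA
  dmu <- dz + (beta / B) * mu
  dlv <- dz * eps * exp(lv / 2) * 0.5 + (beta / B) * 0.5 * (exp(lv) - 1)

  H <- enc$A[[n_enc + 1]]
  g$mu_W <- crossprod(H, dmu); g$mu_b <- matrix(colSums(dmu), 1)
  g$lv_W <- crossprod(H, dlv); g$lv_b <- matrix(colSums(dlv), 1)
  dA <- dmu %*% t(P$mu_W) + dlv %*% t(P$lv_W)
  for (i in rev(seq_len(n_enc))) {
    dZ <- dA * (enc$A[[i + 1]] > 0)
    g[[paste0("enc", i, "_W")]] <- crossprod(enc$A[[i]], dZ)
    g[[paste0("enc", i, "_b")]] <- matrix(colSums(dZ), 1)
    dA <- dZ %*% t(P[[paste0("enc", i, "_W")]])
  }
  list(loss = loss, recon = recon, kl = kl, grads = g)
}

#' Train a VAE on waveform traces
#'
#' Reparameterization-trick sampling, Adam optimization. Traces are divided
#' by one global constant (the maximum absolute value over the training set)
#' so relative peak heights are preserved. Training is fully reproducible for
#' a given seed. The per-epoch loss components are recorded in the model's
#' `history`, and the posterior means of the training set are stored for
#' latent traversal.
#'
#' The KL weight defaults to the likelihood-consistent value for a Gaussian
#' decoder whose variance matches the measurement-noise floor: writing the
#' negative evidence lower bound with decoder variance `sigma^2` and
#' rescaling by `2*sigma^2` gives `SSE + 2*sigma^2 * KL`, so
#' `beta = 2*sigma_hat^2` with `sigma_hat^2` the per-sample noise variance in
#' normalized units, estimated robustly from the median second-difference
#' variance of the training traces (`Var(y'') = 6*sigma^2` for white noise).
#' A fixed `beta` can be supplied instead.
#'
#' @param model A `vae_model` from [init_vae()].
#' @param traces Training traces, one per row (>= 10 rows).
#' @param epochs Training epochs (default 500); `epochs = 0` returns the
#'   model unchanged.
#' @param batch_size Minibatch size (default 16).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed for shuffling and latent sampling.
#' @param beta KL weight; `NULL` (default) self-calibrates as described.
#' @return The trained `vae_model` (with `beta` and `history` recorded).
#' @export
train_vae <- function(model, traces, epochs = 500, batch_size = 16,
                      learning_rate = 1e-3, seed = 1L, beta = NULL) {
  stopifnot(inherits(model, "vae_model"))
  if (epochs == 0) return(model)
  X <- .as_trace_matrix(traces, model$arch$input_dim)
  if (nrow(X) < 10) stop("need at least 10 training traces")
  model$norm_const <- max(abs(X))
  if (model$norm_const == 0) model$norm_const <- 1
  Xn <- X / model$norm_const
  if (is.null(beta)) {
    d2 <- Xn[, -(1:2), drop = FALSE] - 2 * Xn[, -c(1, ncol(Xn)), drop = FALSE] +
      Xn[, -((ncol(Xn) - 1):ncol(Xn)), drop = FALSE]
    sigma2_hat <- median(apply(d2, 1, var)) / 6
    beta <- max(2 * sigma2_hat, 1e-8)
  }
  model$beta <- beta
  n <- nrow(Xn)
  d <- model$arch$latent_dim

  set.seed(seed)
  m_st <- lapply(model$params, function(p) p * 0)
  v_st <- lapply(model$params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  t <- 0
  hist <- matrix(NA_real_, epochs, 3)
  for (e in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    tot <- c(0, 0, 0)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1, n)]
      eps <- matrix(rnorm(length(idx) * d), length(idx), d)
      gr <- .vae_grad(model, Xn[idx, , drop = FALSE], eps, beta)
      if (!is.finite(gr$loss)) {
        stop(sprintf("training error: non-finite loss at epoch %d", e))
      }
      t <- t + 1
      for (nm in names(model$params)) {
        g <- gr$grads[[nm]]
        m_st[[nm]] <- b1 * m_st[[nm]] + (1 - b1) * g
        v_st[[nm]] <- b2 * v_st[[nm]] + (1 - b2) * g^2
        mhat <- m_st[[nm]] / (1 - b1^t)
        vhat <- v_st[[nm]] / (1 - b2^t)
        model$params[[nm]] <- model$params[[nm]] -
          learning_rate * mhat / (sqrt(vhat) + eps_adam)
      }
      tot <- tot + c(gr$recon, gr$kl, gr$loss) * length(idx)
    }
    hist[e, ] <- tot / n
  }
  model$history <- data.frame(epoch = seq_len(epochs),
                              reconstruction = hist[, 1],
                              kl = hist[, 2], total = hist[, 3])
  model$train_mu <- .vae_encode_full(model, Xn)$mu
  model
}

#' Denoise traces by VAE reconstruction
#'
#' Decodes the posterior mean of each trace: `decode(mu(encode(trace)))`,
#' de-normalized to raw signal units.
#'
#' @param model A trained `vae_model` (an untrained model triggers a warning
#'   and proceeds).
#' @param traces Vector (one trace) or matrix of traces.
#' @return Reconstruction with the same shape as the input.
#' @export
reconstruct <- function(model, traces) {
  X <- .as_trace_matrix(traces, model$arch$input_dim)
  nc <- .norm_const_of(model, X)
  enc <- .vae_encode_full(model, X / nc)
  out <- .vae_decode_full(model, enc$mu)$out * nc
  if (is.null(dim(traces))) as.numeric(out) else out
}

#' Fit the PRAA-aligned axis in latent space
#'
#' Least-squares fit of PRAA on the posterior means; the axis direction is
#' the unit coefficient vector and the slope its norm (degrees per latent
#' unit).
#'
#' @param codes Matrix of posterior means (one eye per row), or the list
#'   returned by [vae_encode()].
#' @param praa PRAA values, degrees (one per eye).
#' @return Object of class `praa_axis`: `direction`, `slope`, `intercept`.
#' @export
fit_praa_axis <- function(codes, praa) {
  mu <- if (is.list(codes) && !is.null(codes$mu)) codes$mu else as.matrix(codes)
  if (nrow(mu) < 3) stop("need at least 3 eyes to fit the PRAA axis")
  if (length(praa) != nrow(mu) || any(!is.finite(praa))) {
    stop("invalid-argument: praa must be finite, one value per code")
  }
  if (all(apply(mu, 2, function(v) max(v) - min(v)) < 1e-12)) {
    stop("degenerate-fit error: all latent means identical")
  }
  fit <- lm.fit(cbind(1, mu), praa)
  w <- fit$coefficients[-1]
  w[is.na(w)] <- 0
  slope <- sqrt(sum(w^2))
  direction <- if (slope > 0) w / slope else c(1, rep(0, length(w) - 1))
  structure(list(direction = unname(direction), slope = unname(slope),
                 intercept = unname(fit$coefficients[1])),
            class = "praa_axis")
}

#' Traverse the latent space along the PRAA axis
#'
#' Decodes `z(s) = center + s * direction` for `s` equally spaced in
#' `[-span, span]`, where `center` is the mean training latent. Frames are
#' returned ordered by decreasing predicted PRAA, emulating an animation of
#' the waveform change associated with decreasing PRAA.
#'
#' @param model A trained `vae_model`.
#' @param axis A [fit_praa_axis()] result.
#' @param span Traversal half-width in latent units; default 2 standard
#'   deviations of the training latents projected on the axis.
#' @param n_frames Number of frames (>= 2).
#' @return Matrix of traces (one frame per row) with attributes `s`
#'   (latent offsets) and `praa_pred` (predicted PRAA), both in frame order.
#' @export
traverse <- function(model, axis, span = NULL, n_frames = 11) {
  stopifnot(inherits(model, "vae_model"), inherits(axis, "praa_axis"))
  if (n_frames < 2) stop("invalid-argument: n_frames must be >= 2")
  if (is.null(model$train_mu)) {
    stop("model has no stored training latents; train it first")
  }
  proj <- as.numeric(model$train_mu %*% axis$direction)
  if (is.null(span)) span <- 2 * sd(proj)
  center <- colMeans(model$train_mu)
  s <- seq(-span, span, length.out = n_frames)
  Z <- outer(s, axis$direction) +
    matrix(center, n_frames, length(center), byrow = TRUE)
  pred <- axis$intercept + axis$slope * as.numeric(Z %*% axis$direction)
  ord <- order(pred, decreasing = TRUE)
  frames <- vae_decode(model, Z[ord, , drop = FALSE])
  attr(frames, "s") <- s[ord]
  attr(frames, "praa_pred") <- pred[ord]
  frames
}

#' Export a latent traversal animation
#'
#' Writes the frames both as a multi-page TIFF animation (each page a
#' rasterized waveform plot) and as a plain CSV (one frame per row) that
#' round-trips the frame values exactly.
#'
#' @param frames Frame matrix from [traverse()] (>= 2 rows).
#' @param path Output TIFF path; the CSV is written alongside with suffix
#'   `_frames.csv`.
#' @param height Raster height in pixels.
#' @return Invisible list with `tiff`, `csv`, `n_frames`.
#' @export
export_animation <- function(frames, path, height = 120) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 2) stop("need at least 2 frames")
  csv_path <- paste0(tools::file_path_sans_ext(path), "_frames.csv")
  df <- as.data.frame(frames)
  names(df) <- sprintf("s%03d", seq_len(ncol(frames)) - 1)
  ok <- tryCatch({
    write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", csv_path)
  rng <- range(frames)
  den <- max(rng[2] - rng[1], 1e-12)
  pages <- lapply(seq_len(nrow(frames)), function(i) {
    img <- matrix(1, height, ncol(frames))  # white background
    rows <- 1 + round((1 - (frames[i, ] - rng[1]) / den) * (height - 1))
    img[cbind(rows, seq_len(ncol(frames)))] <- 0
    img
  })
  tryCatch(tiff::writeTIFF(pages, path),
           error = function(e) stop("I/O error: cannot write ", path,
                                    ": ", conditionMessage(e)))
  invisible(list(tiff = path, csv = csv_path, n_frames = nrow(frames)))
}

#' Read traversal frames back from the exported CSV
#'
#' @param csv_path Path written by [export_animation()].
#' @return Frame matrix (one frame per row).
#' @export
read_animation_frames <- function(csv_path) {
  as.matrix(read.csv(csv_path))
}

#' @export
print.vae_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf("VAE %d -> [%s] -> %d -> [%s] -> %d (%d parameters)%s\n",
              a$input_dim, paste(a$encoder_hidden, collapse = ", "),
              a$latent_dim, paste(a$decoder_hidden, collapse = ", "),
              a$input_dim, vae_n_params(a),
              if (is.null(x$norm_const)) ", untrained" else ", trained"))
  invisible(x)
}

#' Save a VAE checkpoint as portable JSON
#'
#' Architecture, normalization constant, seed, and all weights are written to
#' a single JSON file with full numeric precision.
#'
#' @param model A `vae_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_vae_checkpoint <- function(model, path) {
  payload <- list(
    arch = unclass(model$arch),
    norm_const = model$norm_const,
    seed = model$seed,
    params = lapply(model$params, function(m) {
      list(dim = dim(m), data = as.numeric(m))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a VAE checkpoint written by [save_vae_checkpoint()]
#'
#' @param path JSON checkpoint path.
#' @return A `vae_model`.
#' @export
load_vae_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- do.call(vae_arch, payload$arch[c("input_dim", "encoder_hidden",
                                           "latent_dim")])
  params <- lapply(payload$params, function(p) {
    matrix(p$data, p$dim[1], p$dim[2])
  })
  structure(list(arch = arch, params = params,
                 norm_const = payload$norm_const,
                 history = data.frame(), train_mu = NULL,
                 seed = payload$seed),
            class = "vae_model")
}
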
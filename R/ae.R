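#' Autoencoder architecture
#'
#' Mirrored fully connected autoencoder: the encoder maps the 375 binned
#' spectral variables through dense layers of 128, 64 and 32 units into a
#' 12-dimensional latent space; the decoder mirrors the encoder back to 375
#' outputs. All hidden layers (including the latent layer) use a leaky
#' rectifier, which is what allows latent features to take negative values;
#' the output layer is linear. Weights are initialized He-normal.
#'
#' @param input_dim Number of input variables.
#' @param encoder_units Hidden-layer widths of the encoder.
#' @param latent_dim Bottleneck width.
#' @param activation_slope Negative slope of the leaky rectifier.
#' @return Object of class `ae_architecture`.
#' @export
ae_architecture <- function(input_dim = 375,
                            encoder_units = c(128, 64, 32),
                            latent_dim = 12,
                            activation_slope = 0.3) {
  stopifnot(input_dim > 0, all(encoder_units > 0), latent_dim > 0)
  if (latent_dim >= min(encoder_units)) {
    stop_labelled("architecture",
                  "latent_dim must be smaller than every encoder layer")
  }
  widths <- c(input_dim, encoder_units, latent_dim,
              rev(encoder_units), input_dim)
  structure(list(input_dim = input_dim,
                 encoder_units = encoder_units,
                 latent_dim = latent_dim,
                 decoder_units = rev(encoder_units),
                 output_dim = input_dim,
                 widths = widths,
                 activation_slope = activation_slope),
            class = "ae_architecture")
}

#' Autoencoder training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param dropout_rate Dropout probability after the hidden layers
#'   (training only; inference is deterministic).
#' @param dropout_latent Also apply dropout to the bottleneck activations.
#'   Off by default: dropping units of a 12-wide code forces redundant,
#'   distributed representations and blunts the sensitivity of individual
#'   latent features, which defeats feature-level screening.
#' @param l2_lambda L2 penalty coefficient on the weights of every dense
#'   layer except the output (`lambda * sum(W^2)` added to the optimized
#'   loss; the reported loss excludes the penalty).
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience (epochs without improvement of
#'   the monitored mean absolute error); best weights are restored.
#' @param validation_fraction Fraction of samples held out (seeded) to
#'   monitor validation MAE; `0` monitors training MAE instead.
#' @param seed Seed for initialization, the validation split and minibatch
#'   shuffling; `NULL` uses the current RNG state.
#' @return Object of class `ae_train_config`.
#' @export
ae_train_config <- function(learning_rate = 1e-4,
                            batch_size = 32,
                            dropout_rate = 0.1,
                            dropout_latent = FALSE,
                            l2_lambda = 1e-4,
                            max_epochs = 5000,
                            patience = 200,
                            validation_fraction = 0.1,
                            seed = NULL) {
  stopifnot(learning_rate > 0, dropout_rate >= 0, dropout_rate < 1,
            l2_lambda >= 0, max_epochs >= 0, batch_size >= 1)
  structure(list(loss = "mae",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate,
                 dropout_latent = isTRUE(dropout_latent),
                 l2_lambda = l2_lambda,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = seed),
            class = "ae_train_config")
}

.leaky <- function(z, s) z * ((z > 0) + s * (z <= 0))
.dleaky <- function(z, s) (z > 0) + s * (z <= 0)

.he_init <- function(widths) {
  L <- length(widths) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(widths[l] * widths[l + 1],
                                  sd = sqrt(2 / widths[l])),
                     widths[l], widths[l + 1])
    b[[l]] <- numeric(widths[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass. `training` enables inverted dropout after each hidden
# activation; inference never drops units.
.ae_forward <- function(weights, x, slope, dropout_rate = 0,
                        training = FALSE, skip_dropout = integer(0)) {
  L <- length(weights$W)
  As <- vector("list", L + 1); Zs <- vector("list", L)
  masks <- vector("list", L)
  A <- x; As[[1]] <- x
  for (l in seq_len(L)) {
    Z <- A %*% weights$W[[l]]
    Z <- Z + rep(weights$b[[l]], each = nrow(Z))
    if (l < L) {
      A <- .leaky(Z, slope)
      if (training && dropout_rate > 0 && !(l %in% skip_dropout)) {
        keep <- (matrix(stats::runif(length(A)), nrow(A)) >= dropout_rate) /
          (1 - dropout_rate)
        A <- A * keep
        masks[[l]] <- keep
      }
    } else {
      A <- Z
    }
    Zs[[l]] <- Z; As[[l + 1]] <- A
  }
  list(out = A, As = As, Zs = Zs, masks = masks)
}

# Backward pass for MAE loss; returns gradients including the L2 term
# (2 * lambda * W on all layers except the output).
.ae_backward <- function(weights, fwd, y, slope, l2) {
  L <- length(weights$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- sign(fwd$out - y) / length(y)
  for (l in L:1) {
    gW[[l]] <- crossprod(fwd$As[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(weights$W[[l]])
      if (!is.null(fwd$masks[[l - 1]])) delta <- delta * fwd$masks[[l - 1]]
      delta <- delta * .dleaky(fwd$Zs[[l - 1]], slope)
    }
  }
  if (l2 > 0) {
    for (l in seq_len(L - 1)) gW[[l]] <- gW[[l]] + 2 * l2 * weights$W[[l]]
  }
  list(W = gW, b = gb)
}

#' Build an (untrained) autoencoder model
#'
#' Initializes weights He-normal under `seed` and returns an unfitted
#' `spectral_ae` object.
#'
#' @param architecture An [ae_architecture()].
#' @param config An [ae_train_config()].
#' @param seed Integer seed for the weight initialization (overrides
#'   `config$seed` if given).
#' @return Object of class `spectral_ae` with `fitted = FALSE`.
#' @export
build_autoencoder <- function(architecture = ae_architecture(),
                              config = ae_train_config(),
                              seed = config$seed %||% 1) {
  weights <- with_seed(seed, .he_init(architecture$widths))
  structure(list(architecture = architecture,
                 config = config,
                 weights = weights,
                 history = data.frame(epoch = integer(),
                                      train_mae = numeric(),
                                      val_mae = numeric()),
                 fitted = FALSE,
                 seed = seed,
                 bin_centers = NULL),
            class = "spectral_ae")
}

#' Number of trainable parameters
#' @param model A `spectral_ae` or `ae_architecture`.
#' @return Integer count of weights plus biases.
#' @export
n_parameters <- function(model) {
  w <- if (inherits(model, "spectral_ae")) model$architecture$widths
       else model$widths
  sum(w[-length(w)] * w[-1] + w[-1])
}

.mae <- function(x, y) mean(abs(x - y))

#' Train an autoencoder
#'
#' Minimizes the mean absolute error between inputs and reconstructions with
#' Adam, minibatches, inverted dropout and an L2 weight penalty on all
#' layers except the output. A seeded validation split monitors MAE for
#' early stopping; the best weights seen are restored. With
#' `max_epochs = 0` the model is returned at initialization with an empty
#' history.
#'
#' @param model A `spectral_ae` from [build_autoencoder()].
#' @param x Numeric matrix, rows = samples, columns = `input_dim` variables.
#' @param bin_centers Optional wavenumber grid of the input variables,
#'   stored on the model for downstream attribution plots.
#' @param verbose Print progress every 100 epochs.
#' @return The fitted `spectral_ae` (weights, per-epoch history,
#'   `fitted = TRUE`).
#' @export
train_autoencoder <- function(model, x, bin_centers = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(model, "spectral_ae"))
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop_labelled("nonfinite", "NaN/Inf in input")
  if (nrow(x) == 0) stop_labelled("empty", "empty training matrix")
  if (ncol(x) != model$architecture$input_dim) {
    stop_labelled("shape", sprintf("input has %d columns; expected %d",
                                   ncol(x), model$architecture$input_dim))
  }
  cfg <- model$config
  slope <- model$architecture$activation_slope
  model$bin_centers <- bin_centers %||% model$bin_centers
  if (cfg$max_epochs == 0) return(model)

  with_seed(model$seed, {
    n <- nrow(x)
    n_val <- if (cfg$validation_fraction > 0)
      max(1L, round(cfg$validation_fraction * n)) else 0L
    if (n_val > 0 && n - n_val >= 2) {
      val_idx <- sample.int(n, n_val)
      x_val <- x[val_idx, , drop = FALSE]
      x_tr <- x[-val_idx, , drop = FALSE]
    } else {
      x_val <- NULL
      x_tr <- x
    }
    w <- model$weights
    L <- length(w$W)
    skip_drop <- if (isTRUE(cfg$dropout_latent)) integer(0)
                 else length(model$architecture$encoder_units) + 1L
    mW <- lapply(w$W, function(m) m * 0); vW <- mW
    mb <- lapply(w$b, function(v) v * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-7; step <- 0
    best <- Inf; best_w <- w; wait <- 0L
    hist_epoch <- integer(0); hist_tr <- numeric(0); hist_val <- numeric(0)
    n_tr <- nrow(x_tr)

    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n_tr)
      starts <- seq(1, n_tr, by = cfg$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1, n_tr)]
        xb <- x_tr[idx, , drop = FALSE]
        fwd <- .ae_forward(w, xb, slope, cfg$dropout_rate, training = TRUE,
                           skip_dropout = skip_drop)
        g <- .ae_backward(w, fwd, xb, slope, cfg$l2_lambda)
        step <- step + 1
        corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
        for (l in seq_len(L)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
          w$W[[l]] <- w$W[[l]] - cfg$learning_rate * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
          w$b[[l]] <- w$b[[l]] - cfg$learning_rate * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      tr_mae <- .mae(.ae_forward(w, x_tr, slope)$out, x_tr)
      val_mae <- if (!is.null(x_val))
        .mae(.ae_forward(w, x_val, slope)$out, x_val) else NA_real_
      hist_epoch <- c(hist_epoch, epoch)
      hist_tr <- c(hist_tr, tr_mae)
      hist_val <- c(hist_val, val_mae)
      monitor <- if (!is.null(x_val)) val_mae else tr_mae
      if (monitor < best) {
        best <- monitor; best_w <- w; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
      if (verbose && epoch %% 100 == 0) {
        message(sprintf("epoch %d: train MAE %.5f, val MAE %.5f",
                        epoch, tr_mae, val_mae))
      }
    }
    model$weights <- best_w
    model$history <- data.frame(epoch = hist_epoch, train_mae = hist_tr,
                                val_mae = hist_val)
    model$fitted <- TRUE
    model
  })
}

#' Fit an autoencoder to a spectral matrix
#'
#' Convenience wrapper: [build_autoencoder()] then [train_autoencoder()].
#'
#' @param x Numeric matrix (samples x variables) or a `processed_spectra`.
#' @param architecture An [ae_architecture()]; the input width defaults to
#'   `ncol(x)`.
#' @param config An [ae_train_config()].
#' @param seed Integer seed controlling initialization, validation split and
#'   shuffling.
#' @param verbose Print progress.
#' @return A fitted `spectral_ae`.
#' @export
autoencoder <- function(x, architecture = NULL,
                        config = ae_train_config(), seed = 1,
                        verbose = FALSE) {
  bin_centers <- NULL
  if (inherits(x, "processed_spectra")) {
    bin_centers <- x$bin_centers
    x <- x$x
  }
  architecture <- architecture %||% ae_architecture(input_dim = ncol(x))
  model <- build_autoencoder(architecture, config, seed)
  train_autoencoder(model, x, bin_centers = bin_centers, verbose = verbose)
}

.check_fitted <- function(model) {
  if (!isTRUE(model$fitted)) {
    stop_labelled("unfitted", "model has not been trained")
  }
}

#' Encode spectra into latent features
#'
#' Deterministic forward pass through the encoder half (dropout disabled);
#' columns are named F1...F12 in layer order. Latent values can be negative
#' because the latent layer uses the leaky rectifier.
#'
#' @param model A fitted `spectral_ae`.
#' @param x Matrix (samples x input_dim) or `processed_spectra`.
#' @return n x latent_dim matrix.
#' @export
encode <- function(model, x) {
  .check_fitted(model)
  if (inherits(x, "processed_spectra")) x <- x$x
  x <- as.matrix(x)
  if (ncol(x) != model$architecture$input_dim) {
    stop_labelled("shape", sprintf("input has %d columns; expected %d",
                                   ncol(x), model$architecture$input_dim))
  }
  n_enc <- length(model$architecture$encoder_units) + 1
  slope <- model$architecture$activation_slope
  A <- x
  for (l in seq_len(n_enc)) {
    Z <- A %*% model$weights$W[[l]]
    Z <- Z + rep(model$weights$b[[l]], each = nrow(Z))
    A <- .leaky(Z, slope)
  }
  colnames(A) <- paste0("F", seq_len(ncol(A)))
  rownames(A) <- rownames(x)
  A
}

#' Decode latent features back to spectra
#'
#' Deterministic forward pass through the decoder half.
#'
#' @param model A fitted `spectral_ae`.
#' @param latent n x latent_dim matrix.
#' @return n x output_dim matrix of reconstructed spectra.
#' @export
decode <- function(model, latent) {
  .check_fitted(model)
  latent <- as.matrix(latent)
  if (ncol(latent) != model$architecture$latent_dim) {
    stop_labelled("shape", sprintf("latent has %d columns; expected %d",
                                   ncol(latent),
                                   model$architecture$latent_dim))
  }
  n_enc <- length(model$architecture$encoder_units) + 1
  L <- length(model$weights$W)
  slope <- model$architecture$activation_slope
  A <- latent
  for (l in (n_enc + 1):L) {
    Z <- A %*% model$weights$W[[l]]
    Z <- Z + rep(model$weights$b[[l]], each = nrow(Z))
    A <- if (l < L) .leaky(Z, slope) else Z
  }
  rownames(A) <- rownames(latent)
  A
}

#' Reconstruction error report
#'
#' Per-sample root mean square error between original and reconstructed
#' spectra, summarized as mean +/- SD across samples.
#'
#' @param x Original matrix (samples x variables).
#' @param x_hat Reconstruction, same shape.
#' @return Object of class `reconstruction_report` with `per_sample_rmse`,
#'   `mean_rmse`, `sd_rmse`.
#' @export
reconstruction_metrics <- function(x, x_hat) {
  x <- as.matrix(x); x_hat <- as.matrix(x_hat)
  if (!all(dim(x) == dim(x_hat))) {
    stop_labelled("shape", "x and x_hat must have identical dimensions")
  }
  rmse <- sqrt(rowMeans((x - x_hat)^2))
  structure(list(per_sample_rmse = rmse,
                 mean_rmse = mean(rmse),
                 sd_rmse = stats::sd(rmse)),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf("reconstruction RMSE: %.4f +/- %.4f (n = %d)\n",
              x$mean_rmse, x$sd_rmse, length(x$per_sample_rmse)))
  invisible(x)
}

#' @export
print.spectral_ae <- function(x, ...) {
  cat("spectral autoencoder:",
      paste(x$architecture$widths, collapse = "-"), "\n")
  cat(sprintf("parameters: %d; fitted: %s\n", n_parameters(x), x$fitted))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("epochs: %d; final training MAE %.4f, validation MAE %.4f\n",
                last$epoch, last$train_mae, last$val_mae))
  }
  invisible(x)
}

#' @export
summary.spectral_ae <- function(object, ...) {
  print(object)
  cat(sprintf("activation: leaky rectifier (slope %.2f); loss: %s\n",
              object$architecture$activation_slope, object$config$loss))
  cat(sprintf("dropout %.2f, L2 %.1e, Adam lr %.1e, batch %d\n",
              object$config$dropout_rate, object$config$l2_lambda,
              object$config$learning_rate, object$config$batch_size))
  invisible(object)
}

#' Reconstruct spectra with a fitted autoencoder
#' @param object A fitted `spectral_ae`.
#' @param newdata Matrix or `processed_spectra` to reconstruct.
#' @param ... Unused.
#' @return Matrix of reconstructions.
#' @export
predict.spectral_ae <- function(object, newdata, ...) {
  decode(object, encode(object, newdata))
}

#' Reconstruction residuals
#' @param object A fitted `spectral_ae`.
#' @param x Data to reconstruct.
#' @param ... Unused.
#' @return Matrix `x - reconstruction`.
#' @export
residuals.spectral_ae <- function(object, x, ...) {
  if (inherits(x, "processed_spectra")) x <- x$x
  as.matrix(x) - predict(object, x)
}

#' Weight matrices of the model
#' @param object A `spectral_ae`.
#' @param ... Unused.
#' @return List with `W` (weight matrices) and `b` (bias vectors).
#' @export
coef.spectral_ae <- function(object, ...) object$weights

#' Plot training history
#' @param x A fitted `spectral_ae`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.spectral_ae <- function(x, ...) {
  if (!nrow(x$history)) stop_labelled("unfitted", "no training history")
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_mae, x$history$val_mae),
                    type = "l", lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "MAE", ...)
  graphics::legend("topright", c("training", "validation"),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

# Sum of squared weights across penalized (non-output) layers.
weight_norm <- function(model) {
  L <- length(model$weights$W)
  sum(vapply(model$weights$W[seq_len(L - 1)],
             function(m) sum(m^2), numeric(1)))
}
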
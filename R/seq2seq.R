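#' Training configuration
#'
#' Defaults follow the training protocol the package targets: 50 epochs,
#' batch size 512, Adam with initial learning rate 0.001 halved every five
#' epochs, mean-squared-error loss, weights initialized from a zero-mean
#' normal distribution with variance 0.01 (standard deviation 0.1), and a
#' 7:3 train:validation split.
#'
#' @param epochs Number of passes over the training split (>= 1).
#' @param batch_size Mini-batch size.
#' @param lr0 Initial learning rate (> 0).
#' @param lr_halving_period_epochs Halve the learning rate every this many
#'   epochs (0-based indexing: the first period trains at `lr0`).
#' @param weight_init_sd Standard deviation of the normal weight
#'   initialization.
#' @param train_fraction Fraction of the dataset used for gradient updates;
#'   the remainder is the validation split.
#' @param seed Integer seed controlling initialization, the split, shuffling
#'   and dropout.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 50L, batch_size = 512L, lr0 = 1e-3,
                            lr_halving_period_epochs = 5L,
                            weight_init_sd = 0.1, train_fraction = 0.7,
                            seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0,
            lr_halving_period_epochs >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_halving_period_epochs = as.integer(lr_halving_period_epochs),
                 optimizer = "adam", loss = "mse",
                 weight_init_sd = weight_init_sd,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "training_config")
}

#' Learning-rate schedule
#'
#' `lr(e) = lr0 * 0.5^floor(e / period)` with 0-based epoch index `e`.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param lr0 Initial learning rate.
#' @param period Halving period in epochs.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, lr0 = 1e-3, period = 5L) {
  lr0 * 0.5^floor(epoch / period)
}

#' Build an untrained sequence-to-sequence model
#'
#' Instantiates the architecture of [model_config()] with freshly
#' initialized weights.  The same seed yields identical initial weights.
#'
#' @param config A [model_config()], or an architecture name.
#' @param seed Integer seed for weight initialization.
#' @param weight_init_sd Normal initialization standard deviation.
#' @return An untrained `cest_seq2seq` object.
#' @export
build_model <- function(config, seed = 1L, weight_init_sd = 0.1) {
  if (is.character(config)) config <- model_config(config)
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  structure(list(config = config, params = .model_init(config, weight_init_sd),
                 trained = FALSE, history = NULL, grids = NULL, seed = seed),
            class = "cest_seq2seq")
}

.chunked_fwd <- function(params, cfg, X, chunk = 2048L) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, cfg$output_len)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    out[s:e, ] <- .model_fwd(params, cfg, X[s:e, , drop = FALSE],
                             training = FALSE)$yhat
  }
  out
}

#' Fit a sequence-to-sequence Z-spectrum reconstructor
#'
#' Trains a network mapping an 11-point sparse Z-spectrum to a 101-point
#' dense Z-spectrum on simulated paired data.  The dataset is split
#' train:validation by a seeded permutation, optimization is mini-batch Adam
#' on the mean-squared error, the learning rate follows [lr_schedule()], and
#' the weights from the best-validation epoch are retained.
#'
#' @param dataset A `cest_dataset` from [generate_dataset()].
#' @param architecture Architecture name, see [model_config()].
#' @param config Optional full [model_config()] (overrides `architecture`).
#' @param tcfg A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return A `cest_seq2seq` object with elements `params` (best-validation
#'   weights), `config`, `training`, `history` (per-epoch data frame with
#'   `epoch`, `lr`, `train_mse`, `val_mse`), `best_epoch`, `split`
#'   (disjoint train/validation row indices), `grids` and `val_mse_untrained`.
#' @seealso [predict.cest_seq2seq()], [generate_dataset()]
#' @export
fit_seq2seq <- function(dataset, architecture = "tcn_lstm", config = NULL,
                        tcfg = training_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "cest_dataset"))
  if (is.null(config)) config <- model_config(architecture)
  stopifnot(inherits(config, "model_config"),
            inherits(tcfg, "training_config"))
  X <- dataset$sparse_z; Y <- dataset$dense_z
  n <- nrow(X)
  if (n < 2) stop("dataset too small to split")
  if (ncol(X) != config$input_len)
    stop("dataset sparse grid length ", ncol(X),
         " does not match model input_len ", config$input_len)
  if (ncol(Y) != config$output_len)
    stop("dataset dense grid length ", ncol(Y),
         " does not match model output_len ", config$output_len)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(tcfg$seed)
  params <- .model_init(config, tcfg$weight_init_sd)
  perm <- sample.int(n)
  # regression-head bias starts at the per-offset mean of the training
  # targets so the optimizer only has to learn the input-dependent structure
  params$head$b <- colMeans(Y[perm[seq_len(floor(tcfg$train_fraction * n))], ,
                              drop = FALSE])
  ntr <- floor(tcfg$train_fraction * n)
  train_idx <- perm[seq_len(ntr)]
  val_idx <- perm[(ntr + 1):n]
  Xtr <- X[train_idx, , drop = FALSE]; Ytr <- Y[train_idx, , drop = FALSE]
  Xva <- X[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

  val_mse <- function(p) mean((.chunked_fwd(p, config, Xva) - Yva)^2)
  mse0 <- val_mse(params)

  adam <- .adam_init(params)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_mse = numeric(), val_mse = numeric())
  best <- list(mse = Inf, params = params, epoch = 0L)
  denom <- config$output_len
  for (ep in seq_len(tcfg$epochs)) {
    lr <- lr_schedule(ep - 1, tcfg$lr0, tcfg$lr_halving_period_epochs)
    ord <- sample.int(ntr)
    tot <- 0; nb <- 0
    for (s in seq(1, ntr, by = tcfg$batch_size)) {
      e <- min(ntr, s + tcfg$batch_size - 1)
      bi <- ord[s:e]
      xb <- Xtr[bi, , drop = FALSE]; yb <- Ytr[bi, , drop = FALSE]
      fw <- .model_fwd(params, config, xb, training = TRUE)
      resid <- fw$yhat - yb
      loss <- mean(resid^2)
      dy <- 2 * resid / (length(bi) * denom)
      grads <- .model_bwd(params, config, fw$cache, dy)
      st <- .adam_step(params, grads, adam, lr)
      params <- st$params; adam <- st$state
      tot <- tot + loss; nb <- nb + 1
    }
    vm <- val_mse(params)
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                   train_mse = tot / nb, val_mse = vm))
    if (vm < best$mse) best <- list(mse = vm, params = params, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.3e  val %.3e", ep, lr,
                      tot / nb, vm))
  }

  structure(list(config = config, training = tcfg, params = best$params,
                 final_params = params, trained = TRUE, history = hist,
                 best_epoch = best$epoch, val_mse_untrained = mse0,
                 split = list(train = train_idx, validation = val_idx),
                 grids = list(sparse = dataset$meta$sparse,
                              dense = dataset$meta$dense),
                 seed = tcfg$seed),
            class = "cest_seq2seq")
}

#' Predict dense Z-spectra from sparse ones
#'
#' Inference is deterministic (dropout disabled).  The model refuses inputs
#' whose length differs from its bound sparse grid.
#'
#' @param object A `cest_seq2seq` model.
#' @param newdata An `n x input_len` matrix of sparse Z-values, a single
#'   length-`input_len` vector, or a [zspectrum()] on the model's sparse
#'   grid.
#' @param ... Unused.
#' @return An `n x output_len` matrix of reconstructed dense Z-values.
#' @export
predict.cest_seq2seq <- function(object, newdata, ...) {
  if (inherits(newdata, "zspectrum")) {
    if (!is.null(object$grids) &&
        !isTRUE(all.equal(newdata$offsets_ppm, object$grids$sparse)))
      stop("spectrum grid does not match the model's bound sparse grid")
    newdata <- matrix(newdata$z, 1)
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$config$input_len)
    stop("input length ", ncol(newdata), " does not match expected ",
         object$config$input_len)
  if (any(!is.finite(newdata))) stop("non-finite inputs")
  .chunked_fwd(object$params, object$config, newdata)
}

#' @export
print.cest_seq2seq <- function(x, ...) {
  cfg <- x$config
  cat("Sequence-to-sequence Z-spectrum reconstructor\n")
  cat("  architecture:", cfg$architecture,
      sprintf("(%d -> %d)", cfg$input_len, cfg$output_len), "\n")
  if (isTRUE(x$trained)) {
    cat(sprintf("  trained %d epochs; best validation MSE %.3e at epoch %d\n",
                nrow(x$history), min(x$history$val_mse), x$best_epoch))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.cest_seq2seq <- function(object, ...) {
  print(object)
  if (isTRUE(object$trained)) {
    cat("  parameters:", length(unlist(object$params)), "\n")
    cat("  split: ", length(object$split$train), "train /",
        length(object$split$validation), "validation\n")
    h <- object$history
    cat(sprintf("  final epoch: lr %.2e train MSE %.3e val MSE %.3e\n",
                h$lr[nrow(h)], h$train_mse[nrow(h)], h$val_mse[nrow(h)]))
  }
  invisible(object)
}

#' @export
coef.cest_seq2seq <- function(object, ...) object$params

#' Plot training history
#'
#' @param x A trained `cest_seq2seq`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cest_seq2seq <- function(x, ...) {
  if (!isTRUE(x$trained)) stop("model is untrained")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"), log = "y",
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Residuals on the validation split
#'
#' @param object A trained `cest_seq2seq`.
#' @param dataset The `cest_dataset` the model was fitted on.
#' @param ... Unused.
#' @return Matrix of validation residuals (reconstructed minus true).
#' @export
residuals.cest_seq2seq <- function(object, dataset, ...) {
  stopifnot(isTRUE(object$trained), inherits(dataset, "cest_dataset"))
  idx <- object$split$validation
  predict(object, dataset$sparse_z[idx, , drop = FALSE]) -
    dataset$dense_z[idx, , drop = FALSE]
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding weights, both configurations, the training
#' history and the bound offset grids.
#'
#' @param model A `cest_seq2seq`.
#' @param path File path.
#' @return `read_model()` returns the `cest_seq2seq`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cest_seq2seq"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  structure(readRDS(path), class = "cest_seq2seq")
}

#' Export training history as CSV
#'
#' @param model A trained `cest_seq2seq`.
#' @param path Output CSV path.
#' @export
write_history <- function(model, path) {
  stopifnot(isTRUE(model$trained))
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
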
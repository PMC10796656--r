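# Architecture assembly: parameter initialization, forward and backward
# passes for the five sequence-to-sequence reconstruction networks.

.ARCHS <- c("rnn", "lstm", "gru", "tcn", "tcn_lstm")

#' Model configuration for a sequence-to-sequence reconstructor
#'
#' Default topologies: `rnn`/`lstm`/`gru` use 2 stacked recurrent layers of
#' hidden size 128 with dropout between the stacked layers and the final
#' hidden state mapped affinely to the output length; `tcn` uses 4 residual
#' blocks of dilated causal convolutions (kernel 3, dilations 1/2/4/8, 64
#' channels, dropout inside blocks) with the last-time-step features mapped
#' affinely to the output; `tcn_lstm` feeds the TCN feature sequence into a
#' 1-layer LSTM (hidden 128) whose final state drives the affine head.
#' Dropout never acts on the feature vector feeding the head, mirroring how
#' stacked-recurrent dropout is conventionally implemented.  Activations are
#' rectified-linear (recurrent gates keep their standard sigmoid/tanh
#' nonlinearities).
#'
#' @param architecture One of `"rnn"`, `"lstm"`, `"gru"`, `"tcn"`,
#'   `"tcn_lstm"`.
#' @param input_len Sparse spectrum length (default 11).
#' @param output_len Dense spectrum length (default 101).
#' @param hidden_size Recurrent hidden width (default 128).
#' @param num_layers Stacked recurrent layers (default 2).
#' @param tcn_channels,tcn_kernel,tcn_dilations TCN block geometry.
#' @param dropout Random-deactivation ratio in `[0, 1)` (default 0.2),
#'   applied between stacked recurrent layers and inside TCN blocks.
#' @return A `model_config` list.
#' @export
model_config <- function(architecture, input_len = 11L, output_len = 101L,
                         hidden_size = 128L, num_layers = 2L,
                         tcn_channels = 64L, tcn_kernel = 3L,
                         tcn_dilations = c(1L, 2L, 4L, 8L), dropout = 0.2) {
  if (!is.character(architecture) || !(architecture %in% .ARCHS))
    stop("unknown architecture '", architecture, "'; expected one of ",
         paste(.ARCHS, collapse = ", "))
  stopifnot(input_len >= 1, output_len >= 1, hidden_size >= 1,
            num_layers >= 1, dropout >= 0, dropout < 1)
  structure(list(architecture = architecture,
                 input_len = as.integer(input_len),
                 output_len = as.integer(output_len),
                 hidden_size = as.integer(hidden_size),
                 num_layers = as.integer(num_layers),
                 tcn_channels = as.integer(tcn_channels),
                 tcn_kernel = as.integer(tcn_kernel),
                 tcn_dilations = as.integer(tcn_dilations),
                 dropout = dropout),
            class = "model_config")
}

# weight initialization: every weight matrix ~ N(0, sd); biases zero except
# the LSTM forget gate (1). Uses the current RNG state.
.model_init <- function(cfg, sd = 0.01) {
  h <- cfg$hidden_size
  layer_init <- switch(cfg$architecture,
                       rnn = .rnn_layer_init, lstm = .lstm_layer_init,
                       gru = .gru_layer_init, NULL)
  p <- list()
  if (cfg$architecture %in% c("rnn", "lstm", "gru")) {
    p$layers <- vector("list", cfg$num_layers)
    for (l in seq_len(cfg$num_layers))
      p$layers[[l]] <- layer_init(if (l == 1) 1L else h, h, sd)
    feat <- h
  }
  if (cfg$architecture %in% c("tcn", "tcn_lstm")) {
    p$blocks <- vector("list", length(cfg$tcn_dilations))
    for (l in seq_along(cfg$tcn_dilations))
      p$blocks[[l]] <- .tcn_block_init(cfg$tcn_kernel,
                                       if (l == 1) 1L else cfg$tcn_channels,
                                       cfg$tcn_channels, sd)
    feat <- cfg$tcn_channels
  }
  if (cfg$architecture == "tcn_lstm") {
    p$lstm <- .lstm_layer_init(cfg$tcn_channels + 1L, h, sd)
    feat <- h
  }
  # affine head plus a linear input->output skip: the deep stack learns the
  # nonlinear correction to a linear reconstruction
  p$head <- list(W = .init_mat(feat, cfg$output_len, sd),
                 Wx = .init_mat(cfg$input_len, cfg$output_len, sd),
                 b = numeric(cfg$output_len))
  p
}

# X: n x input_len matrix -> list(yhat = n x output_len, cache)
.model_fwd <- function(params, cfg, X, training = FALSE) {
  n <- nrow(X); Tn <- cfg$input_len
  arch <- cfg$architecture
  cache <- list(X = X, n = n)
  # time-major (n*Tn) x 1 layout: row block t is the batch at step t
  S <- matrix(as.vector(X), ncol = 1)
  if (arch %in% c("rnn", "lstm", "gru")) {
    fwd <- switch(arch, rnn = .rnn_layer_fwd, lstm = .lstm_layer_fwd,
                  gru = .gru_layer_fwd)
    cache$layers <- vector("list", cfg$num_layers)
    # dropout sits between stacked layers only, never on the final state
    cache$drops <- vector("list", cfg$num_layers)
    for (l in seq_len(cfg$num_layers)) {
      out <- fwd(S, params$layers[[l]], n, Tn)
      cache$layers[[l]] <- out$cache
      S <- out$H
      if (training && cfg$dropout > 0 && l < cfg$num_layers) {
        m <- .drop_mask(nrow(S), ncol(S), cfg$dropout)
        S <- S * m
        cache$drops[[l]] <- m
      }
    }
    feat <- S[((Tn - 1) * n + 1):(Tn * n), , drop = FALSE]
  } else {
    cache$blocks <- vector("list", length(cfg$tcn_dilations))
    for (l in seq_along(cfg$tcn_dilations)) {
      out <- .tcn_block_fwd(S, params$blocks[[l]], cfg$tcn_dilations[l],
                            n, Tn, cfg$dropout, training)
      cache$blocks[[l]] <- out$cache
      S <- out$out
    }
    if (arch == "tcn_lstm") {
      # LSTM consumes the TCN features concatenated with the raw Z value,
      # keeping a direct input path alongside the convolutional one
      SX <- cbind(S, as.vector(X))
      out <- .lstm_layer_fwd(SX, params$lstm, n, Tn)
      cache$lstm <- out$cache
      feat <- out$H[((Tn - 1) * n + 1):(Tn * n), , drop = FALSE]
    } else {
      feat <- S[((Tn - 1) * n + 1):(Tn * n), , drop = FALSE]
    }
  }
  cache$feat <- feat
  yhat <- feat %*% params$head$W + X %*% params$head$Wx +
    rep(params$head$b, each = n)
  list(yhat = yhat, cache = cache)
}

# dy: n x output_len gradient of the loss w.r.t. yhat -> gradient tree
.model_bwd <- function(params, cfg, cache, dy) {
  Tn <- cfg$input_len
  arch <- cfg$architecture
  g <- list()
  n <- cache$n
  g$head <- list(W = crossprod(cache$feat, dy),
                 Wx = crossprod(cache$X, dy), b = colSums(dy))
  dfeat <- dy %*% t(params$head$W)
  last <- ((Tn - 1) * n + 1):(Tn * n)
  if (arch %in% c("rnn", "lstm", "gru")) {
    bwd <- switch(arch, rnn = .rnn_layer_bwd, lstm = .lstm_layer_bwd,
                  gru = .gru_layer_bwd)
    g$layers <- vector("list", cfg$num_layers)
    dH <- matrix(0, n * Tn, ncol(dfeat))
    dH[last, ] <- dfeat
    for (l in cfg$num_layers:1) {
      out <- bwd(dH, cache$layers[[l]], params$layers[[l]], n, Tn)
      g$layers[[l]] <- out$grads
      dH <- out$dS
      if (l > 1 && !is.null(cache$drops[[l - 1]]))
        dH <- dH * cache$drops[[l - 1]]
    }
  } else {
    ch <- cfg$tcn_channels
    if (arch == "tcn_lstm") {
      dH <- matrix(0, n * Tn, ncol(dfeat))
      dH[last, ] <- dfeat
      lb <- .lstm_layer_bwd(dH, cache$lstm, params$lstm, n, Tn)
      g$lstm <- lb$grads
      dS <- lb$dS[, seq_len(ch), drop = FALSE]  # last column: raw input
    } else {
      dS <- matrix(0, n * Tn, ch)
      dS[last, ] <- dfeat
    }
    g$blocks <- vector("list", length(cfg$tcn_dilations))
    for (l in length(cfg$tcn_dilations):1) {
      out <- .tcn_block_bwd(dS, cache$blocks[[l]], params$blocks[[l]],
                            cfg$tcn_dilations[l], n, Tn)
      g$blocks[[l]] <- out$grads
      dS <- out$dS
    }
  }
  g
}
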
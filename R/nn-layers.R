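# Neural-network layer wrappers.  Sequences are stored time-major as a
# single (batch*T) x C matrix whose row block t is the batch at time step t;
# the fused forward/backward kernels live in src/nn_kernels.cpp.

.sigm <- function(x) 1 / (1 + exp(-x))

.init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

# inverted dropout mask; NULL when not training or rate 0
.drop_mask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(dim1 * dim2) >= rate) / (1 - rate), dim1, dim2)
}

## ---- recurrent layers (ReLU RNN, LSTM, GRU) --------------------------------

.rnn_layer_init <- function(n_in, n_h, sd) {
  list(W = .init_mat(n_in + n_h, n_h, sd), b = numeric(n_h))
}

.rnn_layer_fwd <- function(S, p, n, Tn) {
  out <- rnn_fwd_cpp(S, p$W, p$b, n, Tn)
  list(H = out$H, cache = list(S = S, H = out$H))
}

.rnn_layer_bwd <- function(dH, cache, p, n, Tn) {
  out <- rnn_bwd_cpp(dH, cache$S, cache$H, p$W, n, Tn)
  list(dS = out$dS, grads = list(W = out$W, b = drop(out$b)))
}

.lstm_layer_init <- function(n_in, n_h, sd) {
  b <- numeric(4 * n_h)
  b[(n_h + 1):(2 * n_h)] <- 1  # forget-gate bias
  list(W = .init_mat(n_in + n_h, 4 * n_h, sd), b = b)
}

.lstm_layer_fwd <- function(S, p, n, Tn) {
  out <- lstm_fwd_cpp(S, p$W, p$b, n, Tn)
  out$S <- S
  list(H = out$H, cache = out)
}

.lstm_layer_bwd <- function(dH, cache, p, n, Tn) {
  out <- lstm_bwd_cpp(dH, cache$S, cache$H, cache$I, cache$F, cache$G,
                      cache$O, cache$C, p$W, n, Tn)
  list(dS = out$dS, grads = list(W = out$W, b = drop(out$b)))
}

.gru_layer_init <- function(n_in, n_h, sd) {
  list(Wrz = .init_mat(n_in + n_h, 2 * n_h, sd), brz = numeric(2 * n_h),
       Wxn = .init_mat(n_in, n_h, sd), bxn = numeric(n_h),
       Whn = .init_mat(n_h, n_h, sd), bhn = numeric(n_h))
}

.gru_layer_fwd <- function(S, p, n, Tn) {
  out <- gru_fwd_cpp(S, p$Wrz, p$brz, p$Wxn, p$bxn, p$Whn, p$bhn, n, Tn)
  out$S <- S
  list(H = out$H, cache = out)
}

.gru_layer_bwd <- function(dH, cache, p, n, Tn) {
  out <- gru_bwd_cpp(dH, cache$S, cache$H, cache$R, cache$Zg, cache$N,
                     cache$Q, p$Wrz, p$Wxn, p$Whn, n, Tn)
  list(dS = out$dS,
       grads = list(Wrz = out$Wrz, brz = drop(out$brz), Wxn = out$Wxn,
                    bxn = drop(out$bxn), Whn = out$Whn, bhn = drop(out$bhn)))
}

## ---- TCN residual block: conv-relu-drop-conv-relu-drop + skip, ReLU --------

.conv_init <- function(k, n_in, n_out, sd) {
  list(W = lapply(seq_len(k), function(j) .init_mat(n_in, n_out, sd)),
       b = numeric(n_out))
}

.tcn_block_init <- function(k, n_in, n_out, sd) {
  list(conv1 = .conv_init(k, n_in, n_out, sd),
       conv2 = .conv_init(k, n_out, n_out, sd),
       res = if (n_in != n_out) .init_mat(n_in, n_out, sd) else NULL)
}

.tcn_block_fwd <- function(S, p, d, n, Tn, dropout = 0, training = FALSE) {
  m1 <- m2 <- NULL
  if (training && dropout > 0) {
    m1 <- .drop_mask(n * Tn, length(p$conv1$b), dropout)
    m2 <- .drop_mask(n * Tn, length(p$conv2$b), dropout)
  }
  out <- tcn_block_fwd_cpp(S, p$conv1$W, p$conv1$b, p$conv2$W, p$conv2$b,
                           p$res, m1, m2, d, n, Tn)
  out$S <- S; out$m1 <- m1; out$m2 <- m2
  list(out = out$out, cache = out)
}

.tcn_block_bwd <- function(dout, cache, p, d, n, Tn) {
  bw <- tcn_block_bwd_cpp(dout, cache$S, cache$a1, cache$r1, cache$a2,
                          cache$pre, p$conv1$W, p$conv2$W, p$res,
                          cache$m1, cache$m2, d, n, Tn)
  list(dS = bw$dS,
       grads = list(conv1 = list(W = bw$dW1, b = drop(bw$db1)),
                    conv2 = list(W = bw$dW2, b = drop(bw$db2)),
                    res = bw$dres))
}

## ---- parameter-tree utilities (Adam works on the flattened tree) ----------

.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    keys <- if (is.null(names(a))) seq_along(a) else names(a)
    for (i in seq_along(a))
      out[[i]] <- if (is.null(a[[i]])) NULL
                  else .tree_map2(a[[i]], b[[keys[[i]]]], f)
    out
  } else f(a, b)
}

.tree_zero <- function(a) {
  if (is.list(a)) lapply(a, function(x) if (is.null(x)) NULL else .tree_zero(x))
  else 0 * a
}

.adam_init <- function(params) list(m = .tree_zero(params),
                                    v = .tree_zero(params), t = 0)

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- .tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- .tree_map2(state$m, state$v,
                    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- .tree_map2(params, upd, `-`)
  list(params = params, state = state)
}
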
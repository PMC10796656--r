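// Fused forward/backward kernels for the sequence models.  Sequences are
// time-major (batch*T) x C matrices: row block t holds the batch at step t.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pade-type tanh with clamping: accurate to ~1e-6 inside the clamp and
// branch-free enough for the compiler to vectorize; gates use matching
// stored-activation derivatives, so training stays self-consistent.
static inline double fast_tanh1(double x) {
  const double xc = x < -4.97 ? -4.97 : (x > 4.97 ? 4.97 : x);
  const double x2 = xc * xc;
  const double a = xc * (135135.0 + x2 * (17325.0 + x2 * (378.0 + x2)));
  const double b = 135135.0 + x2 * (62370.0 + x2 * (3150.0 + x2 * 28.0));
  return a / b;
}

static inline arma::mat fast_tanh(const arma::mat& x) {
  arma::mat out(x.n_rows, x.n_cols);
  const double* xi = x.memptr();
  double* oi = out.memptr();
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i) oi[i] = fast_tanh1(xi[i]);
  return out;
}

static inline arma::mat sigm(const arma::mat& x) {
  arma::mat out(x.n_rows, x.n_cols);
  const double* xi = x.memptr();
  double* oi = out.memptr();
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    oi[i] = 0.5 * (1.0 + fast_tanh1(0.5 * xi[i]));
  return out;
}

// zero-copy views over R memory (R owns the data; never resized here)
#define MVIEW(x) arma::mat(REAL(x), Rf_nrows(x), Rf_ncols(x), false, true)
#define VVIEW(x) arma::vec(REAL(x), Rf_xlength(x), false, true)

// ---- plain ReLU recurrence -------------------------------------------------

// [[Rcpp::export]]
List rnn_fwd_cpp(SEXP S_s, SEXP W_s, SEXP b_s, int n, int T) {
  const arma::mat S = MVIEW(S_s);
  const arma::mat W = MVIEW(W_s);
  const arma::vec b = VVIEW(b_s);

  const int in = S.n_cols, h = W.n_cols;
  arma::mat H(n * T, h);
  arma::mat hprev(n, h, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat Z = arma::join_rows(S.rows(t * n, (t + 1) * n - 1), hprev);
    arma::mat A = Z * W;
    A.each_row() += b.t();
    hprev = A % (A > 0);
    H.rows(t * n, (t + 1) * n - 1) = hprev;
  }
  return List::create(Named("H") = H);
}

// [[Rcpp::export]]
List rnn_bwd_cpp(SEXP dH_s, SEXP S_s, SEXP H_s, SEXP W_s, int n, int T) {
  const arma::mat dH = MVIEW(dH_s);
  const arma::mat S = MVIEW(S_s);
  const arma::mat H = MVIEW(H_s);
  const arma::mat W = MVIEW(W_s);

  const int in = S.n_cols, h = W.n_cols;
  arma::mat dS(S.n_rows, in, arma::fill::zeros);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::rowvec db(h, arma::fill::zeros);
  arma::mat dh_next(n, h, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::mat Ht = H.rows(t * n, (t + 1) * n - 1);
    arma::mat dh = dH.rows(t * n, (t + 1) * n - 1) + dh_next;
    arma::mat da = dh % (Ht > 0);
    arma::mat hprev = (t == 0) ? arma::mat(n, h, arma::fill::zeros)
                               : arma::mat(H.rows((t - 1) * n, t * n - 1));
    arma::mat Z = arma::join_rows(S.rows(t * n, (t + 1) * n - 1), hprev);
    dW += Z.t() * da;
    db += arma::sum(da, 0);
    arma::mat dZ = da * W.t();
    dS.rows(t * n, (t + 1) * n - 1) = dZ.cols(0, in - 1);
    dh_next = dZ.cols(in, in + h - 1);
  }
  return List::create(Named("dS") = dS, Named("W") = dW,
                      Named("b") = arma::vec(db.t()));
}

// ---- LSTM ------------------------------------------------------------------

// [[Rcpp::export]]
List lstm_fwd_cpp(SEXP S_s, SEXP W_s, SEXP b_s, int n, int T) {
  const arma::mat S = MVIEW(S_s);
  const arma::mat W = MVIEW(W_s);
  const arma::vec b = VVIEW(b_s);

  const int in = S.n_cols, h = W.n_cols / 4;
  arma::mat H(n * T, h), I(n * T, h), F(n * T, h), G(n * T, h), O(n * T, h),
      C(n * T, h);
  arma::mat hprev(n, h, arma::fill::zeros), cprev(n, h, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat Z = arma::join_rows(S.rows(t * n, (t + 1) * n - 1), hprev);
    arma::mat A = Z * W;
    A.each_row() += b.t();
    arma::mat It = sigm(A.cols(0, h - 1));
    arma::mat Ft = sigm(A.cols(h, 2 * h - 1));
    arma::mat Gt = fast_tanh(A.cols(2 * h, 3 * h - 1));
    arma::mat Ot = sigm(A.cols(3 * h, 4 * h - 1));
    cprev = Ft % cprev + It % Gt;
    hprev = Ot % fast_tanh(cprev);
    const arma::span r(t * n, (t + 1) * n - 1);
    H.rows(r) = hprev; I.rows(r) = It; F.rows(r) = Ft; G.rows(r) = Gt;
    O.rows(r) = Ot; C.rows(r) = cprev;
  }
  return List::create(Named("H") = H, Named("I") = I, Named("F") = F,
                      Named("G") = G, Named("O") = O, Named("C") = C);
}

// [[Rcpp::export]]
List lstm_bwd_cpp(SEXP dH_s, SEXP S_s, SEXP H_s, SEXP I_s, SEXP F_s, SEXP G_s, SEXP O_s, SEXP C_s, SEXP W_s, int n, int T) {
  const arma::mat dH = MVIEW(dH_s);
  const arma::mat S = MVIEW(S_s);
  const arma::mat H = MVIEW(H_s);
  const arma::mat I = MVIEW(I_s);
  const arma::mat F = MVIEW(F_s);
  const arma::mat G = MVIEW(G_s);
  const arma::mat O = MVIEW(O_s);
  const arma::mat C = MVIEW(C_s);
  const arma::mat W = MVIEW(W_s);

  const int in = S.n_cols, h = W.n_cols / 4;
  arma::mat dS(S.n_rows, in, arma::fill::zeros);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::rowvec db(4 * h, arma::fill::zeros);
  arma::mat dh_next(n, h, arma::fill::zeros), dc_next(n, h, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const arma::span r(t * n, (t + 1) * n - 1);
    arma::mat It = I.rows(r), Ft = F.rows(r), Gt = G.rows(r), Ot = O.rows(r);
    arma::mat tc = fast_tanh(arma::mat(C.rows(r)));
    arma::mat cprev = (t == 0) ? arma::mat(n, h, arma::fill::zeros)
                               : arma::mat(C.rows((t - 1) * n, t * n - 1));
    arma::mat hprev = (t == 0) ? arma::mat(n, h, arma::fill::zeros)
                               : arma::mat(H.rows((t - 1) * n, t * n - 1));
    arma::mat dh = dH.rows(r) + dh_next;
    arma::mat dc = dc_next + dh % Ot % (1 - tc % tc);
    arma::mat da = arma::join_rows(
        dc % Gt % It % (1 - It), dc % cprev % Ft % (1 - Ft),
        dc % It % (1 - Gt % Gt), dh % tc % Ot % (1 - Ot));
    arma::mat Z = arma::join_rows(S.rows(r), hprev);
    dW += Z.t() * da;
    db += arma::sum(da, 0);
    arma::mat dZ = da * W.t();
    dS.rows(r) = dZ.cols(0, in - 1);
    dh_next = dZ.cols(in, in + h - 1);
    dc_next = dc % Ft;
  }
  return List::create(Named("dS") = dS, Named("W") = dW,
                      Named("b") = arma::vec(db.t()));
}

// ---- GRU -------------------------------------------------------------------

// [[Rcpp::export]]
List gru_fwd_cpp(SEXP S_s, SEXP Wrz_s, SEXP brz_s, SEXP Wxn_s, SEXP bxn_s, SEXP Whn_s, SEXP bhn_s, int n, int T) {
  const arma::mat S = MVIEW(S_s);
  const arma::mat Wrz = MVIEW(Wrz_s);
  const arma::vec brz = VVIEW(brz_s);
  const arma::mat Wxn = MVIEW(Wxn_s);
  const arma::vec bxn = VVIEW(bxn_s);
  const arma::mat Whn = MVIEW(Whn_s);
  const arma::vec bhn = VVIEW(bhn_s);

  const int in = S.n_cols, h = Whn.n_cols;
  arma::mat H(n * T, h), R(n * T, h), Zg(n * T, h), N(n * T, h), Q(n * T, h);
  arma::mat hprev(n, h, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    const arma::span r(t * n, (t + 1) * n - 1);
    arma::mat X = S.rows(r);
    arma::mat A = arma::join_rows(X, hprev) * Wrz;
    A.each_row() += brz.t();
    arma::mat Rt = sigm(A.cols(0, h - 1));
    arma::mat Zt = sigm(A.cols(h, 2 * h - 1));
    arma::mat Qt = hprev * Whn;
    Qt.each_row() += bhn.t();
    arma::mat pre = X * Wxn;
    pre.each_row() += bxn.t();
    arma::mat Nt = fast_tanh(pre + Rt % Qt);
    hprev = (1 - Zt) % Nt + Zt % hprev;
    H.rows(r) = hprev; R.rows(r) = Rt; Zg.rows(r) = Zt; N.rows(r) = Nt;
    Q.rows(r) = Qt;
  }
  return List::create(Named("H") = H, Named("R") = R, Named("Zg") = Zg,
                      Named("N") = N, Named("Q") = Q);
}

// [[Rcpp::export]]
List gru_bwd_cpp(SEXP dH_s, SEXP S_s, SEXP H_s, SEXP R_s, SEXP Zg_s, SEXP N_s, SEXP Q_s, SEXP Wrz_s, SEXP Wxn_s, SEXP Whn_s, int n, int T) {
  const arma::mat dH = MVIEW(dH_s);
  const arma::mat S = MVIEW(S_s);
  const arma::mat H = MVIEW(H_s);
  const arma::mat R = MVIEW(R_s);
  const arma::mat Zg = MVIEW(Zg_s);
  const arma::mat N = MVIEW(N_s);
  const arma::mat Q = MVIEW(Q_s);
  const arma::mat Wrz = MVIEW(Wrz_s);
  const arma::mat Wxn = MVIEW(Wxn_s);
  const arma::mat Whn = MVIEW(Whn_s);

  const int in = S.n_cols, h = Whn.n_cols;
  arma::mat dS(S.n_rows, in, arma::fill::zeros);
  arma::mat dWrz(Wrz.n_rows, Wrz.n_cols, arma::fill::zeros);
  arma::mat dWxn(Wxn.n_rows, Wxn.n_cols, arma::fill::zeros);
  arma::mat dWhn(Whn.n_rows, Whn.n_cols, arma::fill::zeros);
  arma::rowvec dbrz(2 * h, arma::fill::zeros), dbxn(h, arma::fill::zeros),
      dbhn(h, arma::fill::zeros);
  arma::mat dh_next(n, h, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const arma::span r(t * n, (t + 1) * n - 1);
    arma::mat Rt = R.rows(r), Zt = Zg.rows(r), Nt = N.rows(r), Qt = Q.rows(r);
    arma::mat X = S.rows(r);
    arma::mat hprev = (t == 0) ? arma::mat(n, h, arma::fill::zeros)
                               : arma::mat(H.rows((t - 1) * n, t * n - 1));
    arma::mat dh = dH.rows(r) + dh_next;
    arma::mat dz = dh % (hprev - Nt);
    arma::mat dn = dh % (1 - Zt);
    arma::mat dh_prev = dh % Zt;
    arma::mat dan = dn % (1 - Nt % Nt);
    dWxn += X.t() * dan;
    dbxn += arma::sum(dan, 0);
    arma::mat dX = dan * Wxn.t();
    arma::mat dr = dan % Qt;
    arma::mat dq = dan % Rt;
    dWhn += hprev.t() * dq;
    dbhn += arma::sum(dq, 0);
    dh_prev += dq * Whn.t();
    arma::mat da = arma::join_rows(dr % Rt % (1 - Rt), dz % Zt % (1 - Zt));
    arma::mat Z = arma::join_rows(X, hprev);
    dWrz += Z.t() * da;
    dbrz += arma::sum(da, 0);
    arma::mat dZC = da * Wrz.t();
    dS.rows(r) = dX + dZC.cols(0, in - 1);
    dh_next = dh_prev + dZC.cols(in, in + h - 1);
  }
  return List::create(Named("dS") = dS, Named("Wrz") = dWrz,
                      Named("brz") = arma::vec(dbrz.t()),
                      Named("Wxn") = dWxn, Named("bxn") = arma::vec(dbxn.t()),
                      Named("Whn") = dWhn, Named("bhn") = arma::vec(dbhn.t()));
}

// ---- dilated causal convolution -------------------------------------------

// [[Rcpp::export]]
arma::mat conv_fwd_cpp(SEXP S_s, const List& W, SEXP b_s, int d, int n, int T) {
  const arma::mat S = MVIEW(S_s);
  const arma::vec b = VVIEW(b_s);

  const int n_out = b.n_elem;
  arma::mat Y(n * T, n_out);
  Y.each_row() = b.t();
  const int k = W.size();
  for (int j = 0; j < k; ++j) {
    const int o = j * d;
    if (o >= T) continue;
    const arma::mat Wj = as<arma::mat>(W[j]);
    if (o == 0) Y += S * Wj;
    else Y.rows(o * n, T * n - 1) += S.rows(0, (T - o) * n - 1) * Wj;
  }
  return Y;
}

// [[Rcpp::export]]
List conv_bwd_cpp(SEXP dY_s, SEXP S_s, const List& W, int d, int n, int T) {
  const arma::mat dY = MVIEW(dY_s);
  const arma::mat S = MVIEW(S_s);

  const int k = W.size();
  arma::mat dS(S.n_rows, S.n_cols, arma::fill::zeros);
  List dW(k);
  for (int j = 0; j < k; ++j) {
    const int o = j * d;
    const arma::mat Wj = as<arma::mat>(W[j]);
    if (o >= T) {
      dW[j] = arma::mat(Wj.n_rows, Wj.n_cols, arma::fill::zeros);
      continue;
    }
    if (o == 0) {
      dW[j] = arma::mat(S.t() * dY);
      dS += dY * Wj.t();
    } else {
      dW[j] = arma::mat(S.rows(0, (T - o) * n - 1).t() *
                        dY.rows(o * n, T * n - 1));
      dS.rows(0, (T - o) * n - 1) += dY.rows(o * n, T * n - 1) * Wj.t();
    }
  }
  return List::create(Named("dS") = dS, Named("W") = dW,
                      Named("b") = arma::vec(arma::sum(dY, 0).t()));
}

// ---- fused TCN residual block ---------------------------------------------
// conv -> ReLU -> (dropout) -> conv -> ReLU -> (dropout) + skip -> ReLU
// Dropout masks are generated R-side (R RNG) and passed in, or R_NilValue.

static arma::mat conv_fwd_in(const arma::mat& S, const List& W,
                             const arma::vec& b, int d, int n, int T) {
  const int n_out = b.n_elem;
  arma::mat Y(n * T, n_out);
  Y.each_row() = b.t();
  for (int j = 0; j < W.size(); ++j) {
    const int o = j * d;
    if (o >= T) continue;
    const arma::mat Wj = as<arma::mat>(W[j]);
    if (o == 0) Y += S * Wj;
    else Y.rows(o * n, T * n - 1) += S.rows(0, (T - o) * n - 1) * Wj;
  }
  return Y;
}

// [[Rcpp::export]]
List tcn_block_fwd_cpp(SEXP S_s, const List& W1, SEXP b1_s, const List& W2,
                       SEXP b2_s, SEXP res_s, SEXP m1_s, SEXP m2_s,
                       int d, int n, int T) {
  const arma::mat S = MVIEW(S_s);
  const arma::vec b1 = VVIEW(b1_s);
  const arma::vec b2 = VVIEW(b2_s);
  arma::mat a1 = conv_fwd_in(S, W1, b1, d, n, T);
  arma::mat r1 = a1 % (a1 > 0);
  if (m1_s != R_NilValue) r1 %= MVIEW(m1_s);
  arma::mat a2 = conv_fwd_in(r1, W2, b2, d, n, T);
  arma::mat r2 = a2 % (a2 > 0);
  if (m2_s != R_NilValue) r2 %= MVIEW(m2_s);
  arma::mat pre;
  if (res_s == R_NilValue) pre = r2 + S;
  else pre = r2 + S * MVIEW(res_s);
  arma::mat out = pre % (pre > 0);
  return List::create(Named("out") = out, Named("a1") = a1, Named("r1") = r1,
                      Named("a2") = a2, Named("pre") = pre);
}

// [[Rcpp::export]]
List tcn_block_bwd_cpp(SEXP dout_s, SEXP S_s, SEXP a1_s, SEXP r1_s,
                       SEXP a2_s, SEXP pre_s, const List& W1, const List& W2,
                       SEXP res_s, SEXP m1_s, SEXP m2_s, int d, int n, int T) {
  const arma::mat dout = MVIEW(dout_s);
  const arma::mat S = MVIEW(S_s);
  const arma::mat a1 = MVIEW(a1_s);
  const arma::mat r1 = MVIEW(r1_s);
  const arma::mat a2 = MVIEW(a2_s);
  const arma::mat pre = MVIEW(pre_s);
  arma::mat dpre = dout % (pre > 0);
  arma::mat dS_skip;
  Rcpp::RObject dres(R_NilValue);  // RObject keeps the allocation protected
  if (res_s == R_NilValue) {
    dS_skip = dpre;
  } else {
    const arma::mat res = MVIEW(res_s);
    dS_skip = dpre * res.t();
    dres = wrap(arma::mat(S.t() * dpre));
  }
  arma::mat da2 = (m2_s == R_NilValue) ? arma::mat(dpre % (a2 > 0))
                                       : arma::mat(dpre % MVIEW(m2_s) % (a2 > 0));
  // conv2 backward
  const int k = W2.size();
  List dW2(k);
  arma::mat dr1(r1.n_rows, r1.n_cols, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int o = j * d;
    const arma::mat Wj = as<arma::mat>(W2[j]);
    if (o >= T) { dW2[j] = arma::mat(Wj.n_rows, Wj.n_cols, arma::fill::zeros); continue; }
    if (o == 0) {
      dW2[j] = arma::mat(r1.t() * da2);
      dr1 += da2 * Wj.t();
    } else {
      dW2[j] = arma::mat(r1.rows(0, (T - o) * n - 1).t() *
                         da2.rows(o * n, T * n - 1));
      dr1.rows(0, (T - o) * n - 1) += da2.rows(o * n, T * n - 1) * Wj.t();
    }
  }
  arma::mat da1 = (m1_s == R_NilValue) ? arma::mat(dr1 % (a1 > 0))
                                       : arma::mat(dr1 % MVIEW(m1_s) % (a1 > 0));
  List dW1(W1.size());
  arma::mat dS(S.n_rows, S.n_cols, arma::fill::zeros);
  for (int j = 0; j < W1.size(); ++j) {
    const int o = j * d;
    const arma::mat Wj = as<arma::mat>(W1[j]);
    if (o >= T) { dW1[j] = arma::mat(Wj.n_rows, Wj.n_cols, arma::fill::zeros); continue; }
    if (o == 0) {
      dW1[j] = arma::mat(S.t() * da1);
      dS += da1 * Wj.t();
    } else {
      dW1[j] = arma::mat(S.rows(0, (T - o) * n - 1).t() *
                         da1.rows(o * n, T * n - 1));
      dS.rows(0, (T - o) * n - 1) += da1.rows(o * n, T * n - 1) * Wj.t();
    }
  }
  dS += dS_skip;
  return List::create(Named("dS") = dS,
                      Named("dW1") = dW1, Named("db1") = arma::vec(arma::sum(da1, 0).t()),
                      Named("dW2") = dW2, Named("db2") = arma::vec(arma::sum(da2, 0).t()),
                      Named("dres") = dres);
}
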
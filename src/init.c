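#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* .Call entries generated by Rcpp attributes */
extern SEXP _cestrecon_bm_system_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_bm_zvalue_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_bm_zspectra_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_rnn_fwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_rnn_bwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_lstm_fwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_lstm_bwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_gru_fwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_gru_bwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_conv_fwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_conv_bwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_tcn_block_fwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _cestrecon_tcn_block_bwd_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

/* deSolve compiled-model routines */
extern void bm_ode_init(void (*odeparms)(int *, double *));
extern void bm_ode_deriv(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
  {"_cestrecon_bm_system_cpp",   (DL_FUNC) &_cestrecon_bm_system_cpp,   8},
  {"_cestrecon_bm_zvalue_cpp",   (DL_FUNC) &_cestrecon_bm_zvalue_cpp,   9},
  {"_cestrecon_bm_zspectra_cpp", (DL_FUNC) &_cestrecon_bm_zspectra_cpp, 9},
  {"_cestrecon_rnn_fwd_cpp",   (DL_FUNC) &_cestrecon_rnn_fwd_cpp,   5},
  {"_cestrecon_rnn_bwd_cpp",   (DL_FUNC) &_cestrecon_rnn_bwd_cpp,   6},
  {"_cestrecon_lstm_fwd_cpp",  (DL_FUNC) &_cestrecon_lstm_fwd_cpp,  5},
  {"_cestrecon_lstm_bwd_cpp",  (DL_FUNC) &_cestrecon_lstm_bwd_cpp, 11},
  {"_cestrecon_gru_fwd_cpp",   (DL_FUNC) &_cestrecon_gru_fwd_cpp,   9},
  {"_cestrecon_gru_bwd_cpp",   (DL_FUNC) &_cestrecon_gru_bwd_cpp,  12},
  {"_cestrecon_conv_fwd_cpp",  (DL_FUNC) &_cestrecon_conv_fwd_cpp,  6},
  {"_cestrecon_conv_bwd_cpp",  (DL_FUNC) &_cestrecon_conv_bwd_cpp,  6},
  {"_cestrecon_tcn_block_fwd_cpp", (DL_FUNC) &_cestrecon_tcn_block_fwd_cpp, 11},
  {"_cestrecon_tcn_block_bwd_cpp", (DL_FUNC) &_cestrecon_tcn_block_bwd_cpp, 14},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"bm_ode_init",  (DL_FUNC) &bm_ode_init,  1},
  {"bm_ode_deriv", (DL_FUNC) &bm_ode_deriv, 6},
  {NULL, NULL, 0}
};

void R_init_cestrecon(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
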
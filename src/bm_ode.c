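/* Compiled derivative dM/dt = A M + b for deSolve (21-state system).
   parms = c(A column-major [441], b [21]). */
#include <R.h>

static double bm_parms[462];

void bm_ode_init(void (*odeparms)(int *, double *)) {
  int n = 462;
  odeparms(&n, bm_parms);
}

void bm_ode_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip) {
  const int n = 21;
  const double *A = bm_parms, *b = bm_parms + n * n;
  for (int i = 0; i < n; ++i) ydot[i] = b[i];
  for (int j = 0; j < n; ++j) {
    const double yj = y[j];
    const double *col = A + j * n;
    for (int i = 0; i < n; ++i) ydot[i] += col[i] * yj;
  }
}
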
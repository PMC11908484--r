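// Fused single-pass training kernels. These mutate their first argument in
// place; callers guarantee exclusive ownership (matrices are created inside
// the training loops or deep-copied on entry), which keeps the optimizer
// allocation-free.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Adam update, in place: m, v and w are the optimizer state and parameters,
// g the gradient. lr_t is the bias-corrected step size
// lr * sqrt(1 - beta2^t) / (1 - beta1^t).
// [[Rcpp::export]]
void adam_update_inplace(NumericVector w, NumericVector m, NumericVector v,
                         NumericVector g, double lr_t, double beta1,
                         double beta2, double eps) {
  R_xlen_t n = w.size();
  double *pw = REAL(w), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * gi;
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    pw[i] -= lr_t * pm[i] / (std::sqrt(pv[i]) + eps);
  }
}

// z += b per column block (column-major: column j spans rows), in place.
// [[Rcpp::export]]
void add_bias_inplace(NumericMatrix z, NumericVector b) {
  int nr = z.nrow(), nc = z.ncol();
  double *pz = REAL(z), *pb = REAL(b);
  for (int j = 0; j < nc; ++j) {
    double bj = pb[j];
    double *col = pz + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) col[i] += bj;
  }
}

// ReLU, in place.
// [[Rcpp::export]]
void relu_inplace(NumericMatrix z) {
  R_xlen_t n = (R_xlen_t)z.nrow() * z.ncol();
  double *pz = REAL(z);
  for (R_xlen_t i = 0; i < n; ++i) if (pz[i] < 0) pz[i] = 0;
}

// ReLU backward: dA *= (act > 0), in place (act is the post-activation).
// [[Rcpp::export]]
void relu_backward_inplace(NumericMatrix dA, NumericMatrix act) {
  R_xlen_t n = (R_xlen_t)dA.nrow() * dA.ncol();
  double *pd = REAL(dA), *pa = REAL(act);
  for (R_xlen_t i = 0; i < n; ++i) if (pa[i] <= 0) pd[i] = 0;
}
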
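#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Elementwise kernels for the MLP training loop. The matrix products go
// through R's BLAS; these fused in-place updates avoid the temporary
// allocations that dominate a pure-R inner loop. All arguments are owned
// exclusively by the training loop, so in-place mutation is safe.

// One Adam update on a parameter block. Mutates w, m, v.
// Arithmetic mirrors: m = b1*m + (1-b1)*g; v = b2*v + (1-b2)*g^2;
// w -= lr * (m/bc1) / (sqrt(v/bc2) + eps)
// [[Rcpp::export(rng = false)]]
void adam_step(NumericVector w, NumericVector m, NumericVector v,
               NumericVector g, double lr, double bc1, double bc2,
               double beta1, double beta2, double eps) {
  R_xlen_t n = w.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    double mi = beta1 * m[i] + (1 - beta1) * gi;
    double vi = beta2 * v[i] + (1 - beta2) * (gi * gi);
    m[i] = mi;
    v[i] = vi;
    w[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
}

// z += bias (recycled over rows), then optionally ReLU. Mutates z.
// [[Rcpp::export(rng = false)]]
void bias_act_inplace(NumericMatrix z, NumericVector b, bool relu) {
  int nr = z.nrow(), nc = z.ncol();
  for (int j = 0; j < nc; ++j) {
    double bj = b[j];
    for (int i = 0; i < nr; ++i) {
      double v = z(i, j) + bj;
      if (relu && v < 0) v = 0;
      z(i, j) = v;
    }
  }
}

// delta *= (activation > 0), the ReLU backward mask. Mutates delta.
// [[Rcpp::export(rng = false)]]
void relu_mask_inplace(NumericMatrix delta, NumericMatrix activation) {
  R_xlen_t n = delta.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (activation[i] <= 0) delta[i] = 0;
  }
}
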
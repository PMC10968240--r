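#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused Adam update, applied in place: p, m and v are owned exclusively by
// the training loop (freshly allocated per replicate in nn_init/adam_init),
// so mutating them avoids ~10 full-size temporaries per parameter per step
// that the equivalent vectorized R expressions would allocate.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector p, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double beta1,
                         double beta2, double c1, double c2, double eps) {
  R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_update_inplace: length mismatch");
  double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    double mi = beta1 * pm[i] + (1.0 - beta1) * gi;
    double vi = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    pp[i] -= lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}
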
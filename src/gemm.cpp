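// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Single-precision GEMM: C = op(A) * op(B) computed with sgemm and returned
// as a double matrix. The networks follow the usual deep-learning numerics
// (float32 accumulation); the hot convolution and dense products go through
// here, roughly halving their cost relative to dgemm.
// [[Rcpp::export]]
NumericMatrix gemm_float(const NumericMatrix& A, const NumericMatrix& B,
                         bool transA = false, bool transB = false) {
  arma::fmat Af(A.nrow(), A.ncol());
  std::copy(A.begin(), A.end(), Af.begin());
  arma::fmat Bf(B.nrow(), B.ncol());
  std::copy(B.begin(), B.end(), Bf.begin());
  arma::fmat Cf;
  if (!transA && !transB)      Cf = Af * Bf;
  else if (transA && !transB)  Cf = Af.t() * Bf;
  else if (!transA && transB)  Cf = Af * Bf.t();
  else                         Cf = Af.t() * Bf.t();
  NumericMatrix C(Cf.n_rows, Cf.n_cols);
  std::copy(Cf.begin(), Cf.end(), C.begin());
  return C;
}
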
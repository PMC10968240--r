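// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 1-D convolution over the embedded bit sequence, plus global max pooling.
// Layout: A is the (B*L x e) embedding activation matrix, column-major in
// (batch b, position i); the convolution has K-wide windows, stride 1 and
// F filters, giving P = L - K + 1 output positions. Arithmetic runs in
// float32 (sgemm), matching common deep-learning numerics.

static const int K = 16, F = 330, L = 167, P = L - K + 1;

static arma::fmat unfold(const arma::fmat& Af, int B, int e) {
  arma::fmat U(B * P, K * e);
  for (int k = 0; k < K; ++k)
    for (int d = 0; d < e; ++d) {
      const float* src = Af.colptr(d);
      float* dst = U.colptr(k * e + d);
      for (int p = 0; p < P; ++p)
        std::memcpy(dst + p * B, src + (p + k) * B, B * sizeof(float));
    }
  return U;
}

// Forward: returns pre-ReLU conv activations Z (B*P x F), pooled ReLU
// maxima Pmax (B x F) and argmax positions AM (B x F, 1-based).
// [[Rcpp::export]]
List conv_pool_forward(const NumericMatrix& A, int B,
                       const NumericMatrix& Wc, const NumericVector& bc) {
  int e = A.ncol();
  arma::fmat Af(A.nrow(), e);
  std::copy(A.begin(), A.end(), Af.begin());
  arma::fmat Wf(Wc.nrow(), Wc.ncol());
  std::copy(Wc.begin(), Wc.end(), Wf.begin());
  arma::fmat U = unfold(Af, B, e);
  arma::fmat Z = U * Wf;
  Z.each_row() += arma::conv_to<arma::frowvec>::from(
      arma::vec(bc.begin(), bc.size()));
  NumericMatrix Pmax(B, F);
  IntegerMatrix AM(B, F);
  for (int f = 0; f < F; ++f) {
    const float* zc = Z.colptr(f);
    for (int b = 0; b < B; ++b) {
      float best = 0.0f;  // ReLU floor
      int arg = 1;
      for (int p = 0; p < P; ++p) {
        float h = zc[b + p * B];
        if (h > best) { best = h; arg = p + 1; }
      }
      Pmax(b, f) = best;
      AM(b, f) = arg;
    }
  }
  NumericMatrix Zout(B * P, F);
  std::copy(Z.begin(), Z.end(), Zout.begin());
  return List::create(_["Z"] = Zout, _["P"] = Pmax, _["AM"] = AM);
}

// Backward: dP flows through the argmax, the ReLU mask (Z > 0) and the
// convolution; returns gradients for Wc, bc and the embedding activations.
// [[Rcpp::export]]
List conv_pool_backward(const NumericMatrix& A, int B,
                        const NumericMatrix& Wc, const NumericMatrix& Z,
                        const NumericMatrix& dP, const IntegerMatrix& AM) {
  int e = A.ncol();
  arma::fmat Af(A.nrow(), e);
  std::copy(A.begin(), A.end(), Af.begin());
  arma::fmat Wf(Wc.nrow(), Wc.ncol());
  std::copy(Wc.begin(), Wc.end(), Wf.begin());
  arma::fmat dZ(B * P, F, arma::fill::zeros);
  for (int f = 0; f < F; ++f)
    for (int b = 0; b < B; ++b) {
      double g = dP(b, f);
      if (g == 0.0) continue;
      int p = AM(b, f) - 1;
      long idx = b + (long)p * B;
      if (Z[idx + (long)f * B * P] > 0.0) dZ(idx, f) = (float)g;
    }
  arma::fmat U = unfold(Af, B, e);
  arma::fmat dWc = U.t() * dZ;
  arma::frowvec dbc = arma::sum(dZ, 0);
  arma::fmat dU = dZ * Wf.t();
  arma::fmat dA(B * L, e, arma::fill::zeros);
  for (int k = 0; k < K; ++k)
    for (int d = 0; d < e; ++d) {
      const float* src = dU.colptr(k * e + d);
      float* dst = dA.colptr(d);
      for (int p = 0; p < P; ++p) {
        float* a = dst + (p + k) * B;
        const float* u = src + p * B;
        for (int b = 0; b < B; ++b) a[b] += u[b];
      }
    }
  NumericMatrix dWcO(dWc.n_rows, dWc.n_cols);
  std::copy(dWc.begin(), dWc.end(), dWcO.begin());
  NumericVector dbcO(F);
  std::copy(dbc.begin(), dbc.end(), dbcO.begin());
  NumericMatrix dAO(dA.n_rows, dA.n_cols);
  std::copy(dA.begin(), dA.end(), dAO.begin());
  return List::create(_["dWc"] = dWcO, _["dbc"] = dbcO, _["dA"] = dAO);
}
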
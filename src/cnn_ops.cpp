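// Hot kernels of the 1D CNN: same-padding convolution via im2col + GEMM,
// and max-pooling. Activations are (B*L) x C matrices, row index
// b + (l-1)*B (batch fastest), matching R's column-major array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// W: (k*Cin) x F with rows ordered (d-1)*Cin + c. Zero ("same") padding of
// (k-1)/2 on the left, the remainder on the right.
// [[Rcpp::export]]
Rcpp::List conv1d_fwd_cpp(const arma::mat& X2, const arma::mat& W, const arma::vec& b,
                          int B, int L, int k) {
  const int Cin = X2.n_cols;
  const int pl = (k - 1) / 2;
  mat Xc((size_t)B * L, (size_t)k * Cin, fill::zeros);
  for (int d = 0; d < k; ++d) {
    const int shift = d - pl;  // source position l + shift
    const int l_lo = std::max(0, -shift);
    const int l_hi = std::min(L, L - shift);
    if (l_lo >= l_hi) continue;
    for (int c = 0; c < Cin; ++c)
      std::memcpy(Xc.colptr((size_t)d * Cin + c) + (size_t)l_lo * B,
                  X2.colptr(c) + (size_t)(l_lo + shift) * B,
                  sizeof(double) * (size_t)(l_hi - l_lo) * B);
  }
  mat Y = Xc * W;
  Y.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("Xc") = Xc);
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& dY, const arma::mat& Xc, const arma::mat& W,
                          int B, int L, int k, int Cin) {
  mat dW = Xc.t() * dY;
  rowvec db = sum(dY, 0);
  mat dXc = dY * W.t();
  const int pl = (k - 1) / 2;
  mat dX2((size_t)B * L, Cin, fill::zeros);
  for (int d = 0; d < k; ++d) {
    const int shift = d - pl;
    const int l_lo = std::max(0, -shift);
    const int l_hi = std::min(L, L - shift);
    if (l_lo >= l_hi) continue;
    for (int c = 0; c < Cin; ++c) {
      double* dst = dX2.colptr(c) + (size_t)(l_lo + shift) * B;
      const double* src = dXc.colptr((size_t)d * Cin + c) + (size_t)l_lo * B;
      const size_t nn = (size_t)(l_hi - l_lo) * B;
      for (size_t i = 0; i < nn; ++i) dst[i] += src[i];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX2, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// idx records the within-window argmax (0-based) for the backward pass.
// Ties keep the earliest position, so pooling is deterministic.
// [[Rcpp::export]]
Rcpp::List maxpool_fwd_cpp(const arma::mat& X2, int B, int L, int p) {
  const int C = X2.n_cols;
  const int Lo = L / p;
  mat Y((size_t)B * Lo, C);
  Rcpp::IntegerMatrix idx(B * Lo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X2.colptr(c);
    double* yc = Y.colptr(c);
    for (int lo = 0; lo < Lo; ++lo)
      for (int b = 0; b < B; ++b) {
        double best = xc[(size_t)(lo * p) * B + b];
        int bj = 0;
        for (int j = 1; j < p; ++j) {
          const double v = xc[(size_t)(lo * p + j) * B + b];
          if (v > best) { best = v; bj = j; }
        }
        yc[(size_t)lo * B + b] = best;
        idx((size_t)lo * B + b, c) = bj;
      }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx,
                            Rcpp::Named("L") = L);
}

// [[Rcpp::export]]
arma::mat maxpool_bwd_cpp(const arma::mat& dY, const Rcpp::IntegerMatrix& idx,
                          int B, int L, int p) {
  const int C = dY.n_cols;
  const int Lo = L / p;
  mat dX((size_t)B * L, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dY.colptr(c);
    double* dxc = dX.colptr(c);
    for (int lo = 0; lo < Lo; ++lo)
      for (int b = 0; b < B; ++b) {
        const int j = idx((size_t)lo * B + b, c);
        dxc[(size_t)(lo * p + j) * B + b] = dyc[(size_t)lo * B + b];
      }
  }
  return dX;
}
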
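// Dilated 1-D convolution forward/backward kernels for the network engine.
//
// Data layout: an R array (batch B, length L, channels C) is column-major,
// so element (b, l, c) sits at b + l*B + c*B*L; viewed as a (B*L) x C
// matrix, a shift along the length axis by s is a shift of the row index
// by s*B. Convolutions therefore reduce to one GEMM per kernel tap on a
// contiguous row range, with the out-of-range rows implementing zero
// padding.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat &x, int B, int L,
                       const Rcpp::List &W, const arma::vec &b,
                       int dilation) {
  const int kernel = W.size();
  const int mid = (kernel + 1) / 2;
  const arma::mat W0 = W[0];
  const int cout = W0.n_cols;
  mat y(x.n_rows, cout);
  y.each_row() = b.t();
  for (int k = 0; k < kernel; ++k) {
    const int s = (k + 1 - mid) * dilation; // y[l] += x[l + s] * W_k
    const arma::mat Wk = Rcpp::as<arma::mat>(W[k]);
    const int off = s * B;
    const int r0 = std::max(0, -off);
    const int r1 = std::min((int)x.n_rows, (int)x.n_rows - off) - 1;
    if (r1 >= r0) {
      y.rows(r0, r1) += x.rows(r0 + off, r1 + off) * Wk;
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::mat &x, int B, int L,
                        const Rcpp::List &W, int dilation,
                        const arma::mat &g) {
  const int kernel = W.size();
  const int mid = (kernel + 1) / 2;
  mat dx(x.n_rows, x.n_cols, fill::zeros);
  Rcpp::List dW(kernel);
  vec db = sum(g, 0).t();
  for (int k = 0; k < kernel; ++k) {
    const int s = (k + 1 - mid) * dilation;
    const arma::mat Wk = Rcpp::as<arma::mat>(W[k]);
    const int off = s * B;
    const int r0 = std::max(0, -off);
    const int r1 = std::min((int)x.n_rows, (int)x.n_rows - off) - 1;
    if (r1 >= r0) {
      dW[k] = Rcpp::wrap(x.rows(r0 + off, r1 + off).t() * g.rows(r0, r1));
      dx.rows(r0 + off, r1 + off) += g.rows(r0, r1) * Wk.t();
    } else {
      dW[k] = Rcpp::wrap(arma::mat(x.n_cols, g.n_cols, fill::zeros));
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
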
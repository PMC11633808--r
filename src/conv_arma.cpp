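// Fused convolution forward/backward using Armadillo (BLAS) on the
// (H, W, N, C) layout. The patch ("im2col") matrix lives only in native
// memory and is rebuilt by the backward pass from the layer input, so no
// large R allocations survive between calls and the R garbage collector
// stays out of the hot path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_fill(const double* px, arma::mat& cols, int H, int W,
                        int N, int C, int k, int pad) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        double* pout = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + kw - pad;
            if (ws < 0 || ws >= W) continue;
            const int base_out = H * (w + W * n);
            const int base_in = H * (ws + W * n) + H * W * N * c;
            const int h0 = std::max(0, pad - kh);
            const int h1 = std::min(H, H + pad - kh);
            for (int h = h0; h < h1; ++h) {
              pout[h + base_out] = px[h + kh - pad + base_in];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericMatrix W_,
                           NumericVector b, IntegerVector dims, int k,
                           int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int rows = H * W * N;
  const arma::mat Wm(W_.begin(), W_.nrow(), W_.ncol(), false);
  const int Cout = Wm.n_cols;
  NumericVector yout(rows * Cout);
  arma::mat Y(yout.begin(), rows, Cout, false);
  if (k == 1) {
    const arma::mat X(x.begin(), rows, C, false);
    Y = X * Wm;
  } else {
    arma::mat cols(rows, k * k * C);
    im2col_fill(x.begin(), cols, H, W, N, C, k, pad);
    Y = cols * Wm;
  }
  Y.each_row() += arma::rowvec(b.begin(), Cout);
  yout.attr("dim") = IntegerVector::create(H, W, N, Cout);
  return yout;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector dy, NumericVector x, NumericMatrix W_,
                  IntegerVector dims, int k, int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int rows = H * W * N;
  const arma::mat Wm(W_.begin(), W_.nrow(), W_.ncol(), false);
  const int Cout = Wm.n_cols;
  const arma::mat dY(dy.begin(), rows, Cout, false);
  NumericVector dxout(rows * C);
  NumericMatrix dWout(W_.nrow(), Cout);
  arma::mat dW(dWout.begin(), W_.nrow(), Cout, false);
  NumericVector dbout(Cout);
  arma::rowvec db = arma::sum(dY, 0);
  std::copy(db.begin(), db.end(), dbout.begin());
  if (k == 1) {
    const arma::mat X(x.begin(), rows, C, false);
    dW = X.t() * dY;
    arma::mat dX(dxout.begin(), rows, C, false);
    dX = dY * Wm.t();
    dxout.attr("dim") = IntegerVector::create(H, W, N, C);
    return List::create(_["dx"] = dxout, _["dW"] = dWout, _["db"] = dbout);
  }
  arma::mat cols(rows, k * k * C);
  im2col_fill(x.begin(), cols, H, W, N, C, k, pad);
  dW = cols.t() * dY;
  arma::mat dcols = dY * Wm.t();
  // col2im scatter-add
  double* pdx = dxout.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        const double* pin = dcols.colptr(col);
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + kw - pad;
            if (ws < 0 || ws >= W) continue;
            const int base_out = H * (w + W * n);
            const int base_in = H * (ws + W * n) + H * W * N * c;
            const int h0 = std::max(0, pad - kh);
            const int h1 = std::min(H, H + pad - kh);
            for (int h = h0; h < h1; ++h) {
              pdx[h + kh - pad + base_in] += pin[h + base_out];
            }
          }
        }
      }
    }
  }
  dxout.attr("dim") = IntegerVector::create(H, W, N, C);
  return List::create(_["dx"] = dxout, _["dW"] = dWout, _["db"] = dbout);
}

// relu: x * (x > 0).
// [[Rcpp::export]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector y(clone(x));
  for (double& v : y) if (v < 0) v = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// dy * (y > 0), where y is the relu output.
// [[Rcpp::export]]
NumericVector relu_grad_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx(clone(dy));
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (y[i] <= 0) dx[i] = 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
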
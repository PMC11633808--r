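// Low-level tensor kernels for the compact CNN engine.
//
// Pooling and upsampling kernels on the (H, W, N, C) column-major layout
// (convolutions live in conv_arma.cpp).

#include <Rcpp.h>
using namespace Rcpp;

// 2x2 max pooling with stride 2 on (H, W, N, C); H and W must be even.
// Returns the pooled tensor and the 1-based linear argmax index into the
// input (first maximum wins on ties).
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x, int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * N * C);
  IntegerVector idx(Ho * Wo * N * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const int plane_in = H * W * (n + N * c);
      const int plane_out = Ho * Wo * (n + N * c);
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          int best = 2 * h + H * (2 * w) + plane_in;
          double bv = px[best];
          const int cand[3] = {
            2 * h + 1 + H * (2 * w) + plane_in,
            2 * h + H * (2 * w + 1) + plane_in,
            2 * h + 1 + H * (2 * w + 1) + plane_in};
          for (int j = 0; j < 3; ++j) {
            if (px[cand[j]] > bv) { bv = px[cand[j]]; best = cand[j]; }
          }
          const int o = h + Ho * w + plane_out;
          y[o] = bv;
          idx[o] = best + 1;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           int H, int W, int N, int C) {
  NumericVector dx(H * W * N * C);
  for (int i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}

// Nearest-neighbour 2x upsampling on (H, W, N, C).
// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x, int H, int W, int N, int C) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * Wo * N * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const int plane_in = H * W * (n + N * c);
      const int plane_out = Ho * Wo * (n + N * c);
      for (int w = 0; w < Wo; ++w) {
        const int base_in = H * (w / 2) + plane_in;
        const int base_out = Ho * w + plane_out;
        for (int h = 0; h < Ho; ++h) {
          y[h + base_out] = px[h / 2 + base_in];
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return y;
}

// Adjoint of upsample2_fwd: sums each 2x2 block of the gradient.
// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector dy, int H, int W, int N, int C) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(H * W * N * C);
  const double* pdy = dy.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const int plane_in = H * W * (n + N * c);
      const int plane_out = Ho * Wo * (n + N * c);
      for (int w = 0; w < Wo; ++w) {
        const int base_in = H * (w / 2) + plane_in;
        const int base_out = Ho * w + plane_out;
        for (int h = 0; h < Ho; ++h) {
          dx[h / 2 + base_in] += pdy[h + base_out];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}
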
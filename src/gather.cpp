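// im2col / col2im gather-scatter kernels for the 1-D convolution engine,
// with padding folded in (zero padding, or edge-excluding reflection).
// These are pure memory movements; doing them in C++ avoids the repeated
// intermediate copies R's array subsetting would make.

#include <Rcpp.h>
using namespace Rcpp;

// Map a (possibly out-of-range) 0-based source position into [0, L) by
// edge-excluding reflection; returns -1 when zero padding applies.
static inline int map_pos(int s, int L, bool reflect) {
  if (s >= 0 && s < L) return s;
  if (!reflect) return -1;
  if (s < 0) s = -s;
  if (s >= L) s = 2 * L - 2 - s;
  if (s < 0 || s >= L) return -1;  // degenerate short inputs
  return s;
}

// x: (C, Lx, n).  Returns (C*K, Lcol*n) with xcol[c + C*k, t + Lcol*b] =
// x[c, t*stride + k - pad, b] (padded reads resolved per `reflect`).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int Lx, int n,
                         int K, int stride, int pad, int Lcol,
                         bool reflect) {
  NumericMatrix out(C * K, Lcol * n);
  const double *src = x.begin();
  double *dst = out.begin();
  for (int b = 0; b < n; ++b) {
    const double *xb = src + (R_xlen_t)b * C * Lx;
    for (int t = 0; t < Lcol; ++t) {
      double *col = dst + ((R_xlen_t)b * Lcol + t) * (C * K);
      int s0 = t * stride - pad;
      if (s0 >= 0 && s0 + K <= Lx) {  // fully interior: one block copy
        memcpy(col, xb + (R_xlen_t)s0 * C, sizeof(double) * C * K);
      } else {
        for (int k = 0; k < K; ++k) {
          int s = map_pos(s0 + k, Lx, reflect);
          if (s < 0)
            memset(col + (R_xlen_t)k * C, 0, sizeof(double) * C);
          else
            memcpy(col + (R_xlen_t)k * C, xb + (R_xlen_t)s * C,
                   sizeof(double) * C);
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add columns into a zeroed (C, Lx, n) array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int C, int Lx, int n,
                         int K, int stride, int pad, int Lcol,
                         bool reflect) {
  NumericVector out((R_xlen_t)C * Lx * n);
  double *dst = out.begin();
  const double *src = cols.begin();
  for (int b = 0; b < n; ++b) {
    double *xb = dst + (R_xlen_t)b * C * Lx;
    for (int t = 0; t < Lcol; ++t) {
      const double *col = src + ((R_xlen_t)b * Lcol + t) * (C * K);
      int s0 = t * stride - pad;
      for (int k = 0; k < K; ++k) {
        int s = map_pos(s0 + k, Lx, reflect);
        if (s < 0) continue;
        double *win = xb + (R_xlen_t)s * C;
        const double *ck = col + (R_xlen_t)k * C;
        for (int c = 0; c < C; ++c) win[c] += ck[c];
      }
    }
  }
  return out;
}
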
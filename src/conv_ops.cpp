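// Patch-matrix kernels for the 3x3 shape-preserving convolutions in R/nn.R.
// Layout contract (column-major R arrays):
//   feature maps  x : (H, W, C, N)
//   patch matrix    : (H*W*N) rows ordered (h, w, n),
//                     9*C cols ordered kr + 3*(kc-1) + 9*(ci-1)
// matching matrix(W, 9*C, Cout) for a (3, 3, C, Cout) weight array.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N) {
  NumericMatrix out(H * W * N, 9 * C);
  const double *xp = x.begin();
  double *op = out.begin();
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  for (int ci = 0; ci < C; ++ci) {
    for (int kc = 0; kc < 3; ++kc) {
      for (int kr = 0; kr < 3; ++kr) {
        const int col = kr + 3 * kc + 9 * ci;
        double *dst = op + (R_xlen_t)col * rows;
        for (int n = 0; n < N; ++n) {
          const double *src = xp + ((R_xlen_t)n * C + ci) * H * W;
          for (int w = 0; w < W; ++w) {
            const int ws = w + kc - 1;
            double *d = dst + ((R_xlen_t)n * W + w) * H;
            if (ws < 0 || ws >= W) {
              for (int h = 0; h < H; ++h) d[h] = 0.0;
            } else {
              const double *s = src + (R_xlen_t)ws * H;
              const int dr = kr - 1;
              for (int h = 0; h < H; ++h) {
                const int hs = h + dr;
                d[h] = (hs >= 0 && hs < H) ? s[hs] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcol, int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double *cp = dcol.begin();
  double *dp = dx.begin();
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  for (int ci = 0; ci < C; ++ci) {
    for (int kc = 0; kc < 3; ++kc) {
      for (int kr = 0; kr < 3; ++kr) {
        const int col = kr + 3 * kc + 9 * ci;
        const double *src = cp + (R_xlen_t)col * rows;
        for (int n = 0; n < N; ++n) {
          double *dst = dp + ((R_xlen_t)n * C + ci) * H * W;
          for (int w = 0; w < W; ++w) {
            const int ws = w + kc - 1;
            if (ws < 0 || ws >= W) continue;
            const double *s = src + ((R_xlen_t)n * W + w) * H;
            double *d = dst + (R_xlen_t)ws * H;
            const int dr = kr - 1;
            for (int h = 0; h < H; ++h) {
              const int hs = h + dr;
              if (hs >= 0 && hs < H) d[hs] += s[h];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
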
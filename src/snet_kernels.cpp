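#include <Rcpp.h>
using namespace Rcpp;

// Dense layer kernels for the s-Net trainer. All activation tensors use the
// column-major layout (H, W, C, N); convolution kernels use (K, K, Cin, Cout)
// with "same" padding and stride 1. Indexing is fully explicit so the layout
// contract with the R side cannot drift.

static inline int idx4(int i, int j, int c, int n, int H, int W, int C) {
  return i + H * (j + W * (c + C * n));
}

// Unfold 3x3 same-padded patches into a (9*Cin) x (H*W*N) matrix so that the
// convolution itself becomes a BLAS matrix product on the R side. Column
// ordering is (i, j, n); row ordering is (ki, kj, ci).
// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, int H, int W, int C, int N) {
  const int K = 3, P = 1, R = K * K * C;
  NumericMatrix cols(R, static_cast<R_xlen_t>(H) * W * N);
  const double *px = x.begin();
  double *pc = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double *col = pc + static_cast<R_xlen_t>(R) * (i + H * (j + static_cast<R_xlen_t>(W) * n));
        for (int ci = 0; ci < C; ++ci) {
          const double *base = px + idx4(0, 0, ci, n, H, W, C);
          for (int kj = 0; kj < K; ++kj) {
            int jj = j + kj - P;
            bool jok = jj >= 0 && jj < W;
            for (int ki = 0; ki < K; ++ki) {
              int ii = i + ki - P;
              col[ki + K * (kj + K * ci)] =
                (jok && ii >= 0 && ii < H) ? base[ii + H * jj] : 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col3: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix cols, int H, int W, int C, int N) {
  const int K = 3, P = 1, R = K * K * C;
  NumericVector x(static_cast<R_xlen_t>(H) * W * C * N);
  double *px = x.begin();
  const double *pc = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double *col = pc + static_cast<R_xlen_t>(R) * (i + H * (j + static_cast<R_xlen_t>(W) * n));
        for (int ci = 0; ci < C; ++ci) {
          double *base = px + idx4(0, 0, ci, n, H, W, C);
          for (int kj = 0; kj < K; ++kj) {
            int jj = j + kj - P;
            if (jj < 0 || jj >= W) continue;
            for (int ki = 0; ki < K; ++ki) {
              int ii = i + ki - P;
              if (ii < 0 || ii >= H) continue;
              base[ii + H * jj] += col[ki + K * (kj + K * ci)];
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2 max pooling, stride 2. Returns pooled values and the 0-based linear
// index (into the input tensor) of each selected maximum for the backward pass.
// Ties break toward the first element in column-major scan order.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x, int H, int W, int C, int N) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector amax(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = amax.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -1e300; int bi = -1;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              int xi = idx4(2 * i + di, 2 * j + dj, c, n, H, W, C);
              if (px[xi] > best) { best = px[xi]; bi = xi; }
            }
          }
          int yi = idx4(i, j, c, n, Ho, Wo, C);
          py[yi] = best;
          pa[yi] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector amax,
                           int H, int W, int C, int N) {
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  const double *pdy = dy.begin();
  const int *pa = amax.begin();
  double *pdx = dx.begin();
  for (R_xlen_t k = 0; k < dy.size(); ++k) pdx[pa[k]] += pdy[k];
  return dx;
}
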
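// Low-level raster kernels for the package's CPU training engine.
// Convolutions are expressed as im2col + BLAS matrix products on the R side;
// these routines only rearrange memory, so they stay allocation-light.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// x: H x W x C cube. Returns (k*k*C) x (oH*oW) matrix.
// Row order matches the flattening of an R k x k x C array (row index
// fastest), so a weight array k x k x Cin x F maps onto it directly.
// [[Rcpp::export]]
arma::mat nn_im2col(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  arma::mat cols(k * k * C, oH * oW, arma::fill::zeros);
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int col = oh + oH * ow;
      const int r0 = oh * stride - pad;
      const int c0 = ow * stride - pad;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kc = 0; kc < k; ++kc) {
          const int cc = c0 + kc;
          for (int kr = 0; kr < k; ++kr) {
            const int rr = r0 + kr;
            if (rr >= 0 && rr < H && cc >= 0 && cc < W)
              dst[kr + k * kc + k * k * c] = x(rr, cc, c);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of nn_im2col: scatter-add columns back onto an H x W x C cube.
// [[Rcpp::export]]
arma::cube nn_col2im(const arma::mat& cols, int H, int W, int C,
                     int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int col = oh + oH * ow;
      const int r0 = oh * stride - pad;
      const int c0 = ow * stride - pad;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kc = 0; kc < k; ++kc) {
          const int cc = c0 + kc;
          for (int kr = 0; kr < k; ++kr) {
            const int rr = r0 + kr;
            if (rr >= 0 && rr < H && cc >= 0 && cc < W)
              x(rr, cc, c) += src[kr + k * kc + k * k * c];
          }
        }
      }
    }
  }
  return x;
}

// 2x2 max pooling, stride 2. Returns pooled cube and flat argmax indices
// (0-based into the input cube, stored as doubles) for the backward pass.
// [[Rcpp::export]]
List nn_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oH = H / 2, oW = W / 2;
  arma::cube out(oH, oW, C);
  arma::cube idx(oH, oW, C);
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        double best = -arma::datum::inf;
        double bi = 0;
        for (int dc = 0; dc < 2; ++dc) {
          for (int dr = 0; dr < 2; ++dr) {
            const int r = 2 * oh + dr, cc = 2 * ow + dc;
            const double v = x(r, cc, c);
            if (v > best) {
              best = v;
              bi = (double)(r + H * cc + H * W * c);
            }
          }
        }
        out(oh, ow, c) = best;
        idx(oh, ow, c) = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube nn_maxpool2_bwd(const arma::cube& dout, const arma::cube& idx,
                           int H, int W) {
  const int C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const arma::uword n = dout.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    dx((arma::uword)idx(i)) += dout(i);
  return dx;
}

// Nearest-neighbour x2 upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
arma::cube nn_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = x(h, w, c);
        out(2 * h, 2 * w, c) = v;
        out(2 * h + 1, 2 * w, c) = v;
        out(2 * h, 2 * w + 1, c) = v;
        out(2 * h + 1, 2 * w + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube nn_upsample2_bwd(const arma::cube& dout) {
  const int H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        dx(h, w, c) = dout(2 * h, 2 * w, c) + dout(2 * h + 1, 2 * w, c) +
                      dout(2 * h, 2 * w + 1, c) + dout(2 * h + 1, 2 * w + 1, c);
  return dx;
}
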
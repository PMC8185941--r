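// Low-level primitives for the compact fully convolutional networks:
// im2col/col2im "same" convolution, 2x2 average pooling, nearest-neighbour
// 2x upsampling. Arrays are arma::cube with (rows = y, cols = x,
// slices = channels), matching R's array(dim = c(H, W, C)) layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Unfold x (H x W x Cin) into (H*W) x (k*k*Cin) with zero "same" padding.
// Column block order: channel-major, then kernel offset row-major
// (dy in -r..r outer, dx inner), so weights reshape consistently.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int r = (k - 1) / 2;
  mat out(H * W, k * k * C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dy = -r; dy <= r; ++dy) {
      for (int dx = -r; dx <= r; ++dx, ++col) {
        // destination rows are column-major over (y, x)
        for (int j = 0; j < W; ++j) {
          const int js = j + dx;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + dy;
            if (is < 0 || is >= H) continue;
            out(i + j * H, col) = x(is, js, c);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: fold gradient columns back onto the input grid.
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& dcol, const int H, const int W,
                      const int C, const int k) {
  const int r = (k - 1) / 2;
  cube out(H, W, C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dy = -r; dy <= r; ++dy) {
      for (int dx = -r; dx <= r; ++dx, ++col) {
        for (int j = 0; j < W; ++j) {
          const int js = j + dx;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + dy;
            if (is < 0 || is >= H) continue;
            out(is, js, c) += dcol(i + j * H, col);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2(const arma::cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                               x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double g = 0.25 * dy(i, j, c);
        out(2 * i, 2 * j, c) = g;
        out(2 * i + 1, 2 * j, c) = g;
        out(2 * i, 2 * j + 1, c) = g;
        out(2 * i + 1, 2 * j + 1, c) = g;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                       dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return out;
}

// Bilinear upsampling by an integer factor with half-pixel alignment;
// used to lift the region-scale tumor probability map to cell scale.
// [[Rcpp::export]]
arma::mat cpp_upsample_bilinear(const arma::mat& x, const int factor) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = H * factor, Wo = W * factor;
  mat out(Ho, Wo);
  for (int j = 0; j < Wo; ++j) {
    const double sx = (j + 0.5) / factor - 0.5;
    int x0 = (int)std::floor(sx);
    double fx = sx - x0;
    if (x0 < 0) { x0 = 0; fx = 0.0; }
    int x1 = x0 + 1 < W ? x0 + 1 : W - 1;
    for (int i = 0; i < Ho; ++i) {
      const double sy = (i + 0.5) / factor - 0.5;
      int y0 = (int)std::floor(sy);
      double fy = sy - y0;
      if (y0 < 0) { y0 = 0; fy = 0.0; }
      int y1 = y0 + 1 < H ? y0 + 1 : H - 1;
      out(i, j) = (1 - fy) * ((1 - fx) * x(y0, x0) + fx * x(y0, x1)) +
                  fy * ((1 - fx) * x(y1, x0) + fx * x(y1, x1));
    }
  }
  return out;
}
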
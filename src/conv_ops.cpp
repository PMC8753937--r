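#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// 3x3 same-padding convolution primitives via im2col + BLAS gemm.
// Weight layout: rows indexed by (channel c, col offset dc, row offset dr)
// as 9*c + 3*(dc+1) + (dr+1); one column per output channel.

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(static_cast<uword>(H) * W, 9 * static_cast<uword>(C), fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const uword k = 9 * c + 3 * (dc + 1) + (dr + 1);
        const int a0 = std::max(0, -dr), a1 = std::min(H - 1, H - 1 - dr);
        const int b0 = std::max(0, -dc), b1 = std::min(W - 1, W - 1 - dc);
        mat shifted(H, W, fill::zeros);
        shifted.submat(a0, b0, a1, b1) =
          x.slice(c).submat(a0 + dr, b0 + dc, a1 + dr, b1 + dc);
        out.col(k) = vectorise(shifted);
      }
    }
  }
  return out;
}

static cube col2im3(const mat& cols, int H, int W, int C) {
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const uword k = 9 * c + 3 * (dc + 1) + (dr + 1);
        const int a0 = std::max(0, -dr), a1 = std::min(H - 1, H - 1 - dr);
        const int b0 = std::max(0, -dc), b1 = std::min(W - 1, W - 1 - dc);
        mat g = reshape(cols.col(k), H, W);
        gx.slice(c).submat(a0 + dr, b0 + dc, a1 + dr, b1 + dc) +=
          g.submat(a0, b0, a1, b1);
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv3_fwd(const arma::cube& x, const arma::mat& Wm,
                         const arma::vec& b) {
  const mat cols = im2col3(x);
  mat y = cols * Wm;
  y.each_row() += b.t();
  cube out(x.n_rows, x.n_cols, Wm.n_cols);
  for (uword o = 0; o < Wm.n_cols; ++o)
    out.slice(o) = reshape(y.col(o), x.n_rows, x.n_cols);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3_bwd(const arma::cube& x, const arma::mat& Wm,
                         const arma::cube& gy) {
  const mat cols = im2col3(x);
  mat gym(x.n_rows * x.n_cols, gy.n_slices);
  for (uword o = 0; o < gy.n_slices; ++o) gym.col(o) = vectorise(gy.slice(o));
  mat gW = cols.t() * gym;
  vec gb = sum(gym, 0).t();
  cube gx = col2im3(gym * Wm.t(), x.n_rows, x.n_cols, x.n_slices);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; argmax index 0..3 encoded as (a + 2*b) for
// offset (a, b) inside the window. Ties keep the first (smallest index).

// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword h = H / 2, w = W / 2;
  cube y(h, w, C), idx(h, w, C);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < w; ++j) {
      for (uword i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            const double v = x(2 * i + a, 2 * j + b, c);
            if (v > best) { best = v; bi = a + 2 * b; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& gy, const arma::cube& idx,
                            int H, int W) {
  const uword h = gy.n_rows, w = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < w; ++j)
      for (uword i = 0; i < h; ++i) {
        const int k = static_cast<int>(idx(i, j, c));
        gx(2 * i + (k % 2), 2 * j + (k / 2), c) += gy(i, j, c);
      }
  return gx;
}
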
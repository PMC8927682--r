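// Dense numeric kernels for the segmentation network.
// Layout convention matches R arrays: cube(H, W, C), column-major,
// element (h, w, c) at h + H*w + H*W*c.
//
// 3x3 convolutions use same-padding im2col + GEMM. Kernel matrices are
// (9*Cin) x Cout with row index k = (dh+1) + 3*(dw+1) + 9*c, i.e. the
// spatial offset runs fastest and the input channel slowest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        const int col = (dh + 1) + 3 * (dw + 1) + 9 * c;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          double* o = out.colptr(col) + H * w;
          const double* xs = x.slice_colptr(c, ws) + dh;
          for (int h = h0; h < h1; ++h) o[h] = xs[h];
        }
      }
  return out;
}

static cube col2im3(const mat& gx_col, int H, int W, int C) {
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        const int col = (dh + 1) + 3 * (dw + 1) + 9 * c;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double* g = gx_col.colptr(col) + H * w;
          double* xs = gx.slice_colptr(c, ws) + dh;
          for (int h = h0; h < h1; ++h) xs[h] += g[h];
        }
      }
  return gx;
}

// [[Rcpp::export]]
arma::cube conv3_fwd(const arma::cube& x, const arma::mat& k,
                     const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cout = k.n_cols;
  mat y = im2col3(x) * k;
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, Cout);
}

// Forward pass returning the im2col matrix too, so the backward pass can
// reuse it instead of rebuilding it.
// [[Rcpp::export]]
Rcpp::List conv3_fwd_cols(const arma::cube& x, const arma::mat& k,
                          const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cout = k.n_cols;
  mat cols = im2col3(x);
  mat y = cols * k;
  y.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("y") = cube(y.memptr(), H, W, Cout),
                            Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd(const arma::mat& cols, const arma::mat& k,
                     const arma::cube& gy, bool need_gx) {
  const int H = gy.n_rows, W = gy.n_cols, Cout = k.n_cols;
  const int C = k.n_rows / 9;
  const mat g(const_cast<double*>(gy.memptr()), H * W, Cout, false, true);
  mat gk = cols.t() * g;
  vec gb = sum(g, 0).t();
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("gx") = R_NilValue, Rcpp::Named("gk") = gk,
      Rcpp::Named("gb") = gb);
  if (need_gx) out["gx"] = col2im3(g * k.t(), H, W, C);
  return out;
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double best = x(2 * h, 2 * w, c);
        int bi = 0;
        const int dhs[4] = {0, 1, 0, 1}, dws[4] = {0, 0, 1, 1};
        for (int t = 1; t < 4; ++t) {
          double v = x(2 * h + dhs[t], 2 * w + dws[t], c);
          if (v > best) { best = v; bi = t; }
        }
        y(h, w, c) = best;
        idx(h, w, c) = bi;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& gy, const arma::icube& idx,
                        int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const int dhs[4] = {0, 1, 0, 1}, dws[4] = {0, 0, 1, 1};
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const int t = idx(h, w, c);
        gx(2 * h + dhs[t], 2 * w + dws[t], c) += gy(h, w, c);
      }
  return gx;
}

// [[Rcpp::export]]
arma::cube avgpool_fwd(const arma::cube& x, int s) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / s, Wo = W / s;
  cube y(Ho, Wo, C, fill::zeros);
  const double inv = 1.0 / (s * s);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double acc = 0.0;
        for (int dw = 0; dw < s; ++dw)
          for (int dh = 0; dh < s; ++dh) acc += x(s * h + dh, s * w + dw, c);
        y(h, w, c) = acc * inv;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube avgpool_bwd(const arma::cube& gy, int s, int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const double inv = 1.0 / (s * s);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double g = gy(h, w, c) * inv;
        for (int dw = 0; dw < s; ++dw)
          for (int dh = 0; dh < s; ++dh) gx(s * h + dh, s * w + dw, c) += g;
      }
  return gx;
}

// Half-pixel-centre bilinear sampling: src = (dst + 0.5) * in/out - 0.5,
// clamped to the valid range, so factor-2 up/down round trips are smooth.
static void bilin_coef(int n_in, int n_out, ivec& i0, ivec& i1, vec& f) {
  i0.set_size(n_out); i1.set_size(n_out); f.set_size(n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int lo = (int)std::floor(s);
    if (lo > n_in - 2) lo = std::max(0, n_in - 2);
    i0(i) = lo;
    i1(i) = std::min(lo + 1, n_in - 1);
    f(i) = s - lo;
  }
}

// [[Rcpp::export]]
arma::cube bilinear_fwd(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  ivec h0, h1, w0, w1; vec fh, fw;
  bilin_coef(H, Ho, h0, h1, fh);
  bilin_coef(W, Wo, w0, w1, fw);
  cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double a = x(h0(h), w0(w), c), b = x(h1(h), w0(w), c);
        const double d = x(h0(h), w1(w), c), e = x(h1(h), w1(w), c);
        y(h, w, c) = (1 - fw(w)) * ((1 - fh(h)) * a + fh(h) * b) +
                     fw(w) * ((1 - fh(h)) * d + fh(h) * e);
      }
  return y;
}

// [[Rcpp::export]]
arma::cube bilinear_bwd(const arma::cube& gy, int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  ivec h0, h1, w0, w1; vec fh, fw;
  bilin_coef(H, Ho, h0, h1, fh);
  bilin_coef(W, Wo, w0, w1, fw);
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double g = gy(h, w, c);
        gx(h0(h), w0(w), c) += (1 - fw(w)) * (1 - fh(h)) * g;
        gx(h1(h), w0(w), c) += (1 - fw(w)) * fh(h) * g;
        gx(h0(h), w1(w), c) += fw(w) * (1 - fh(h)) * g;
        gx(h1(h), w1(w), c) += fw(w) * fh(h) * g;
      }
  return gx;
}
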
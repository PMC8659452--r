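// Minimal convolution kernels for the native runtime.
// Activations are H x W x C cubes; weights for standard convs are
// (Cout x k*k*Cin) matrices with row layout ((c*k + ky)*k + kx), depthwise
// weights are (k*k x C) matrices. Padding is darknet-style "same"
// (pad = k / 2 for odd k; 3x3 stride-2 convs use pad 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, int k, int stride, int pad, int ho, int wo) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  mat cols(k * k * c, ho * wo, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    const mat& plane = x.slice(ch);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int r = (ch * k + ky) * k + kx;
        for (int ox = 0; ox < wo; ++ox) {
          const int sx = ox * stride + kx - pad;
          if (sx < 0 || sx >= w) continue;
          for (int oy = 0; oy < ho; ++oy) {
            const int sy = oy * stride + ky - pad;
            if (sy < 0 || sy >= h) continue;
            cols(r, oy + ox * ho) = plane(sy, sx);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, int k, int stride, int pad,
                   int h, int w, int c, int ho, int wo) {
  cube x(h, w, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    mat& plane = x.slice(ch);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int r = (ch * k + ky) * k + kx;
        for (int ox = 0; ox < wo; ++ox) {
          const int sx = ox * stride + kx - pad;
          if (sx < 0 || sx >= w) continue;
          for (int oy = 0; oy < ho; ++oy) {
            const int sy = oy * stride + ky - pad;
            if (sy < 0 || sy >= h) continue;
            plane(sy, sx) += cols(r, oy + ox * ho);
          }
        }
      }
    }
  }
  return x;
}

static int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::vec& bias, int k, int stride, int pad) {
  const int ho = out_dim(x.n_rows, k, stride, pad);
  const int wo = out_dim(x.n_cols, k, stride, pad);
  mat cols = im2col(x, k, stride, pad, ho, wo);
  mat y = w * cols;                       // (Cout x ho*wo)
  if (bias.n_elem == (unsigned) y.n_rows) y.each_col() += bias;
  cube out(ho, wo, y.n_rows);
  for (unsigned co = 0; co < y.n_rows; ++co) {
    out.slice(co) = reshape(y.row(co), ho, wo);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy, int k, int stride, int pad,
                          bool has_bias) {
  const int ho = dy.n_rows, wo = dy.n_cols, co = dy.n_slices;
  mat dym(co, ho * wo);
  for (int i = 0; i < co; ++i) dym.row(i) = vectorise(dy.slice(i)).t();
  mat cols = im2col(x, k, stride, pad, ho, wo);
  mat dw = dym * cols.t();
  mat dcols = w.t() * dym;
  cube dx = col2im(dcols, k, stride, pad, x.n_rows, x.n_cols, x.n_slices, ho, wo);
  vec db;
  if (has_bias) db = sum(dym, 1);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube dwconv_fwd_cpp(const arma::cube& x, const arma::mat& w,
                          int k, int stride, int pad) {
  const int ho = out_dim(x.n_rows, k, stride, pad);
  const int wo = out_dim(x.n_cols, k, stride, pad);
  const int h = x.n_rows, wd = x.n_cols, c = x.n_slices;
  cube out(ho, wo, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    const mat& plane = x.slice(ch);
    mat& o = out.slice(ch);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const double wv = w((ky)*k + kx, ch);
        if (wv == 0) continue;
        for (int ox = 0; ox < wo; ++ox) {
          const int sx = ox * stride + kx - pad;
          if (sx < 0 || sx >= wd) continue;
          for (int oy = 0; oy < ho; ++oy) {
            const int sy = oy * stride + ky - pad;
            if (sy < 0 || sy >= h) continue;
            o(oy, ox) += wv * plane(sy, sx);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List dwconv_bwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy, int k, int stride, int pad) {
  const int ho = dy.n_rows, wo = dy.n_cols;
  const int h = x.n_rows, wd = x.n_cols, c = x.n_slices;
  cube dx(h, wd, c, fill::zeros);
  mat dw(k * k, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    const mat& plane = x.slice(ch);
    const mat& dyp = dy.slice(ch);
    mat& dxp = dx.slice(ch);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const double wv = w(ky * k + kx, ch);
        double acc = 0;
        for (int ox = 0; ox < wo; ++ox) {
          const int sx = ox * stride + kx - pad;
          if (sx < 0 || sx >= wd) continue;
          for (int oy = 0; oy < ho; ++oy) {
            const int sy = oy * stride + ky - pad;
            if (sy < 0 || sy >= h) continue;
            const double g = dyp(oy, ox);
            acc += g * plane(sy, sx);
            dxp(sy, sx) += g * wv;
          }
        }
        dw(ky * k + kx, ch) = acc;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw);
}

// [[Rcpp::export]]
Rcpp::List maxpool_fwd_cpp(const arma::cube& x, int k, int stride, int pad) {
  const int ho = out_dim(x.n_rows, k, stride, pad);
  const int wo = out_dim(x.n_cols, k, stride, pad);
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  cube y(ho, wo, c);
  Rcpp::IntegerVector idx(ho * wo * c);
  int p = 0;
  for (int ch = 0; ch < c; ++ch) {
    const mat& plane = x.slice(ch);
    for (int ox = 0; ox < wo; ++ox) {
      for (int oy = 0; oy < ho; ++oy) {
        double best = -datum::inf;
        int besti = -1;
        for (int ky = 0; ky < k; ++ky) {
          const int sy = oy * stride + ky - pad;
          if (sy < 0 || sy >= h) continue;
          for (int kx = 0; kx < k; ++kx) {
            const int sx = ox * stride + kx - pad;
            if (sx < 0 || sx >= w) continue;
            const double v = plane(sy, sx);
            if (v > best) { best = v; besti = ch * h * w + sx * h + sy; }
          }
        }
        y(oy, ox, ch) = best;
        idx[ch * ho * wo + ox * ho + oy] = besti;
        ++p;
      }
    }
  }
  (void) p;
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd_cpp(const arma::cube& dy, const Rcpp::IntegerVector& idx,
                           int h, int w, int c) {
  cube dx(h, w, c, fill::zeros);
  const double* src = dy.memptr();
  double* dst = dx.memptr();
  for (int i = 0; i < (int) dy.n_elem; ++i) dst[idx[i]] += src[i];
  return dx;
}

// training-mode forward that also returns the im2col matrix for reuse in
// the backward pass
// [[Rcpp::export]]
Rcpp::List conv2d_fwd_cols_cpp(const arma::cube& x, const arma::mat& w,
                               const arma::vec& bias, int k, int stride, int pad) {
  const int ho = out_dim(x.n_rows, k, stride, pad);
  const int wo = out_dim(x.n_cols, k, stride, pad);
  mat cols = im2col(x, k, stride, pad, ho, wo);
  mat y = w * cols;
  if (bias.n_elem == (unsigned) y.n_rows) y.each_col() += bias;
  cube out(ho, wo, y.n_rows);
  for (unsigned co = 0; co < y.n_rows; ++co) {
    out.slice(co) = reshape(y.row(co), ho, wo);
  }
  return Rcpp::List::create(Rcpp::Named("y") = out, Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cols_cpp(const arma::mat& cols, const arma::mat& w,
                               const arma::cube& dy, int k, int stride, int pad,
                               int h, int wdt, int c, bool has_bias) {
  const int ho = dy.n_rows, wo = dy.n_cols, co = dy.n_slices;
  mat dym(co, ho * wo);
  for (int i = 0; i < co; ++i) dym.row(i) = vectorise(dy.slice(i)).t();
  mat dw = dym * cols.t();
  mat dcols = w.t() * dym;
  cube dx = col2im(dcols, k, stride, pad, h, wdt, c, ho, wo);
  vec db;
  if (has_bias) db = sum(dym, 1);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
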
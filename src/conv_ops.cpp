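// Convolution primitives for the separated-path wavelet SR network.
// Layout convention: feature tensors are R arrays [H, W, C, N] (column-major),
// dense kernels are [k, k, Cin, Cout], depthwise kernels are [k, k, C].
// All convolutions are cross-correlations with zero "same" padding (k odd).
//
// Dense convolutions run as one batched GEMM over an (H*W*N) x (k*k*Cin)
// im2col matrix held in single precision (the standard precision for CNN
// arithmetic; parameters and their updates stay in double on the R side).
// The im2col matrix can be cached in a numbered slot during the forward
// pass and reused by the matching backward call, and the element-wise
// activation is fused into the convolution to avoid extra full-tensor
// passes in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// activation codes
enum { ACT_LINEAR = 0, ACT_RELU = 1, ACT_TANH = 2 };

static inline IntegerVector dims_of(const NumericVector &x, int need) {
  IntegerVector d = x.attr("dim");
  if (d.size() != need) stop("expected a %d-d array", need);
  return d;
}

// Fill rows [row0, row0+H*W) of the im2col matrix from one sample.
// Column r = kh + k*(kw + k*c) holds the (kh, kw)-shifted plane of
// channel c, zero outside the image.
static void im2col_rows(const double *x, int H, int W, int C, int k,
                        arma::fmat &col, size_t row0) {
  const int p = k / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * HW;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        float *dst = col.colptr(kh + k * (kw + k * c)) + row0;
        const int dh = kh - p, dw = kw - p;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          float *d = dst + (size_t)w * H;
          if (ws < 0 || ws >= W) {
            std::fill(d, d + H, 0.0f);
            continue;
          }
          const double *s = xc + (size_t)ws * H;
          const int h_lo = std::max(0, -dh), h_hi = std::min(H, H - dh);
          for (int h = 0; h < h_lo; ++h) d[h] = 0.0f;
          for (int h = h_lo; h < h_hi; ++h) d[h] = (float)s[h + dh];
          for (int h = h_hi; h < H; ++h) d[h] = 0.0f;
        }
      }
    }
  }
}

// Adjoint: scatter-add the column block of one sample back onto the image.
static void col2im_rows(const arma::fmat &col, size_t row0, int H, int W,
                        int C, int k, double *x) {
  const int p = k / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double *xc = x + (size_t)c * HW;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const float *src = col.colptr(kh + k * (kw + k * c)) + row0;
        const int dh = kh - p, dw = kw - p;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          const float *s = src + (size_t)w * H;
          double *d = xc + (size_t)ws * H;
          const int h_lo = std::max(0, -dh), h_hi = std::min(H, H - dh);
          for (int h = h_lo; h < h_hi; ++h) d[h + dh] += s[h];
        }
      }
    }
  }
}

// scratch buffers (single-threaded R)
static arma::fmat &scratch(int which, size_t nr, size_t nc) {
  static arma::fmat bufs[3];
  bufs[which].set_size(nr, nc);
  return bufs[which];
}

// im2col cache slots written by the forward pass, reused by backward
#define N_CACHE_SLOTS 16
static arma::fmat cache_slots[N_CACHE_SLOTS];

static inline void build_col_all(const double *x, int H, int W, int C,
                                 int k, int N, arma::fmat &col) {
  const size_t HW = (size_t)H * W;
  col.set_size(HW * N, (size_t)k * k * C);
  for (int n = 0; n < N; ++n)
    im2col_rows(x + (size_t)n * HW * C, H, W, C, k, col, (size_t)n * HW);
}

static arma::fmat to_fmat(const double *p, size_t nr, size_t nc) {
  arma::fmat m(nr, nc);
  const size_t len = nr * nc;
  float *d = m.memptr();
  for (size_t i = 0; i < len; ++i) d[i] = (float)p[i];
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int act = 0,
                             int cache_slot = -1) {
  IntegerVector dx = dims_of(x, 4), dw = dims_of(w, 4);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k || k % 2 == 0) stop("kernel must be square with odd size");
  if (Cin != C) stop("input has %d channels but kernel expects %d", C, Cin);
  if (b.size() != Cout) stop("bias length must equal output channels");
  if (cache_slot >= N_CACHE_SLOTS) stop("cache slot out of range");

  const int K = k * k * C;
  const size_t HW = (size_t)H * W;
  // kernel as (K x Cout): row order identical to the R array layout
  const arma::fmat Wm = to_fmat(&w[0], K, Cout);
  arma::fmat out;
  if (k == 1) {
    out.set_size(HW * N, Cout);
    for (int n = 0; n < N; ++n) {
      const arma::fmat Xn =
        to_fmat(&x[0] + (size_t)n * HW * C, HW, C);
      out.rows((size_t)n * HW, (size_t)(n + 1) * HW - 1) = Xn * Wm;
    }
  } else {
    arma::fmat &col = (cache_slot >= 0) ? cache_slots[cache_slot]
                                        : scratch(0, 1, 1);
    build_col_all(&x[0], H, W, C, k, N, col);
    out = col * Wm; // (HW*N) x Cout
  }

  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int co = 0; co < Cout; ++co) {
    const float *src = out.colptr(co);
    const double bc = b[co];
    for (int n = 0; n < N; ++n) {
      double *dst = &y[0] + ((size_t)n * Cout + co) * HW;
      const float *s = src + (size_t)n * HW;
      switch (act) {
      case ACT_RELU:
        for (size_t i = 0; i < HW; ++i) {
          const double v = s[i] + bc;
          dst[i] = v > 0 ? v : 0;
        }
        break;
      case ACT_TANH:
        for (size_t i = 0; i < HW; ++i) dst[i] = std::tanh(s[i] + bc);
        break;
      default:
        for (size_t i = 0; i < HW; ++i) dst[i] = s[i] + bc;
      }
    }
  }
  return y;
}

// Backward through activation + convolution. `y` is the forward output
// (post-activation), `dy` the gradient wrt y; the activation derivative
// is recovered from y (relu: y > 0; tanh: 1 - y^2).
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector y,
                    NumericVector dy, int act = 0, int cache_slot = -1) {
  IntegerVector dx_ = dims_of(x, 4), dw_ = dims_of(w, 4), dd = dims_of(dy, 4);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], Cout = dw_[3];
  if (dd[0] != H || dd[1] != W || dd[2] != Cout || dd[3] != N)
    stop("gradient shape mismatch");
  if (act != ACT_LINEAR && y.size() != dy.size())
    stop("activation backward needs the forward output");
  if (cache_slot >= N_CACHE_SLOTS) stop("cache slot out of range");
  const int K = k * k * C;
  const size_t HW = (size_t)H * W;

  const arma::fmat Wm = to_fmat(&w[0], K, Cout);

  // dz = dy * act'(z), laid out (HW*N) x Cout
  arma::fmat &dY = scratch(1, HW * N, Cout);
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    float *dst = dY.colptr(co);
    double acc = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * Cout + co) * HW;
      const double *g = &dy[0] + off;
      float *d = dst + (size_t)n * HW;
      if (act == ACT_RELU) {
        const double *yv = &y[0] + off;
        for (size_t i = 0; i < HW; ++i) {
          const double v = yv[i] > 0 ? g[i] : 0.0;
          d[i] = (float)v;
          acc += v;
        }
      } else if (act == ACT_TANH) {
        const double *yv = &y[0] + off;
        for (size_t i = 0; i < HW; ++i) {
          const double v = g[i] * (1.0 - yv[i] * yv[i]);
          d[i] = (float)v;
          acc += v;
        }
      } else {
        for (size_t i = 0; i < HW; ++i) {
          d[i] = (float)g[i];
          acc += g[i];
        }
      }
    }
    gb[co] = acc;
  }

  NumericVector gw(w.size()), gx(x.size());
  gw.attr("dim") = w.attr("dim");
  gx.attr("dim") = x.attr("dim");

  if (k == 1) {
    arma::fmat dWm(K, Cout, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      const arma::fmat Xn = to_fmat(&x[0] + (size_t)n * HW * C, HW, C);
      const arma::fmat dYn = dY.rows((size_t)n * HW, (size_t)(n + 1) * HW - 1);
      dWm += Xn.t() * dYn;
      arma::fmat dXn = dYn * Wm.t(); // HW x C
      double *gxn = &gx[0] + (size_t)n * HW * C;
      const float *s = dXn.memptr();
      for (size_t i = 0; i < HW * (size_t)C; ++i) gxn[i] = s[i];
    }
    for (int i = 0; i < K * Cout; ++i) gw[i] = dWm.memptr()[i];
  } else {
    arma::fmat &col = (cache_slot >= 0 &&
                       cache_slots[cache_slot].n_rows == HW * N &&
                       cache_slots[cache_slot].n_cols == (size_t)K)
                        ? cache_slots[cache_slot]
                        : scratch(0, 1, 1);
    if (col.n_rows != HW * N || col.n_cols != (size_t)K)
      build_col_all(&x[0], H, W, C, k, N, col);
    arma::fmat dWm = col.t() * dY; // K x Cout
    for (int i = 0; i < K * Cout; ++i) gw[i] = dWm.memptr()[i];
    arma::fmat &dcol = scratch(2, HW * N, K);
    dcol = dY * Wm.t(); // (HW*N) x K
    for (int n = 0; n < N; ++n)
      col2im_rows(dcol, (size_t)n * HW, H, W, C, k,
                  &gx[0] + (size_t)n * HW * C);
  }
  return List::create(_["dx"] = gx, _["dw"] = gw, _["db"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fwd(NumericVector x, NumericVector w,
                               int act = 0) {
  IntegerVector dx = dims_of(x, 4), dw = dims_of(w, 3);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0];
  if (dw[1] != k || k % 2 == 0) stop("kernel must be square with odd size");
  if (dw[2] != C) stop("depthwise kernel channel mismatch");
  const int p = k / 2;
  const size_t HW = (size_t)H * W;

  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = &x[0] + ((size_t)n * C + c) * HW;
      const double *wc = &w[0] + (size_t)c * k * k;
      double *yc = &y[0] + ((size_t)n * C + c) * HW;
      for (int kw = 0; kw < k; ++kw) {
        const int dw_ = kw - p;
        for (int kh = 0; kh < k; ++kh) {
          const int dh = kh - p;
          const double wv = wc[kh + k * kw];
          if (wv == 0.0) continue;
          const int w_lo = std::max(0, -dw_), w_hi = std::min(W, W - dw_);
          const int h_lo = std::max(0, -dh), h_hi = std::min(H, H - dh);
          for (int wcol = w_lo; wcol < w_hi; ++wcol) {
            const double *s = xc + (size_t)(wcol + dw_) * H + dh;
            double *d = yc + (size_t)wcol * H;
            for (int h = h_lo; h < h_hi; ++h) d[h] += wv * s[h];
          }
        }
      }
      if (act == ACT_RELU) {
        for (size_t i = 0; i < HW; ++i)
          if (yc[i] < 0) yc[i] = 0;
      } else if (act == ACT_TANH) {
        for (size_t i = 0; i < HW; ++i) yc[i] = std::tanh(yc[i]);
      }
    }
  return y;
}

// `y` is the forward (post-activation) output when act != linear.
// [[Rcpp::export]]
List cpp_dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector y,
                      NumericVector dy, int act = 0) {
  IntegerVector dx_ = dims_of(x, 4), dw_ = dims_of(w, 3);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], p = k / 2;
  const size_t HW = (size_t)H * W;
  if (dy.size() != x.size()) stop("gradient shape mismatch");
  if (act != ACT_LINEAR && y.size() != dy.size())
    stop("activation backward needs the forward output");

  // dz = dy * act'(z), recovered from the stored output
  NumericVector dz;
  if (act == ACT_LINEAR) {
    dz = dy;
  } else {
    dz = NumericVector(dy.size());
    if (act == ACT_RELU) {
      for (R_xlen_t i = 0; i < dy.size(); ++i)
        dz[i] = y[i] > 0 ? dy[i] : 0.0;
    } else {
      for (R_xlen_t i = 0; i < dy.size(); ++i)
        dz[i] = dy[i] * (1.0 - y[i] * y[i]);
    }
  }
  NumericVector gx(x.size()), gw(w.size());
  gx.attr("dim") = x.attr("dim");
  gw.attr("dim") = w.attr("dim");
  dy = dz;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = &x[0] + ((size_t)n * C + c) * HW;
      const double *wc = &w[0] + (size_t)c * k * k;
      const double *dyc = &dy[0] + ((size_t)n * C + c) * HW;
      double *gxc = &gx[0] + ((size_t)n * C + c) * HW;
      double *gwc = &gw[0] + (size_t)c * k * k;
      for (int kw = 0; kw < k; ++kw) {
        const int dw2 = kw - p;
        for (int kh = 0; kh < k; ++kh) {
          const int dh = kh - p;
          const double wv = wc[kh + k * kw];
          double acc = 0.0;
          const int w_lo = std::max(0, -dw2), w_hi = std::min(W, W - dw2);
          const int h_lo = std::max(0, -dh), h_hi = std::min(H, H - dh);
          for (int wcol = w_lo; wcol < w_hi; ++wcol) {
            const double *s = xc + (size_t)(wcol + dw2) * H + dh;
            double *gd = gxc + (size_t)(wcol + dw2) * H + dh;
            const double *g = dyc + (size_t)wcol * H;
            for (int h = h_lo; h < h_hi; ++h) {
              acc += g[h] * s[h];
              gd[h] += g[h] * wv;
            }
          }
          gwc[kh + k * kw] += acc;
        }
      }
    }
  return List::create(_["dx"] = gx, _["dw"] = gw);
}
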
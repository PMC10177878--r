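// Numerical kernels for the network layers: plain and deformable convolution,
// 2x bilinear resampling, 2x2 average pooling, ROIAlign and point-wise
// bilinear sampling.  Every forward kernel has a matching backward kernel so
// the R-level tape can train the model.
//
// Layout conventions:
//   feature maps  : arma::cube (H rows, W cols, C slices) == R array c(H,W,C)
//   conv weights  : flat vector, index ki + K*(kj + K*(c + C*o)), 0-based
//   spatial coords: y = row, x = col
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int wdim(const NumericVector& w, int i) {
  IntegerVector d = w.attr("dim");
  return d[i];
}

// ---------------------------------------------------------------- im2col ----
static arma::mat im2col(const arma::cube& x, int K, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(K * K * C, (size_t)Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t cidx = (size_t)ho + (size_t)Ho * wo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < K; ++kj) {
          const int iw = wo * stride - pad + kj;
          if (iw < 0 || iw >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int ih = ho * stride - pad + ki;
            if (ih < 0 || ih >= H) continue;
            col(ki + K * (kj + K * c), cidx) = x(ih, iw, c);
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(arma::cube& gx, const arma::mat& col, int K, int stride,
                       int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t cidx = (size_t)ho + (size_t)Ho * wo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < K; ++kj) {
          const int iw = wo * stride - pad + kj;
          if (iw < 0 || iw >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int ih = ho * stride - pad + ki;
            if (ih < 0 || ih >= H) continue;
            gx(ih, iw, c) += col(ki + K * (kj + K * c), cidx);
          }
        }
      }
    }
  }
}

// ------------------------------------------------------------------ conv ----
// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const NumericVector& w,
                          const NumericVector& b, int stride, int pad) {
  const int K = wdim(w, 0), C = wdim(w, 2), O = wdim(w, 3);
  if ((int)x.n_slices != C) stop("conv2d: channel mismatch");
  const int Ho = (x.n_rows + 2 * pad - K) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - K) / stride + 1;
  arma::mat col = im2col(x, K, stride, pad, Ho, Wo);
  const arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, O, false, true);
  arma::mat Y = Wm.t() * col;              // O x (Ho*Wo)
  arma::cube out(Ho, Wo, O);
  for (int o = 0; o < O; ++o)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        out(ho, wo, o) = Y(o, (size_t)ho + (size_t)Ho * wo) + b[o];
  return out;
}

// forward that also returns the im2col matrix for reuse in backward
// [[Rcpp::export]]
List cpp_conv2d_fwd_cache(const arma::cube& x, const NumericVector& w,
                          const NumericVector& b, int stride, int pad) {
  const int K = wdim(w, 0), C = wdim(w, 2), O = wdim(w, 3);
  if ((int)x.n_slices != C) stop("conv2d: channel mismatch");
  const int Ho = (x.n_rows + 2 * pad - K) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - K) / stride + 1;
  arma::mat col = im2col(x, K, stride, pad, Ho, Wo);
  const arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, O, false, true);
  arma::mat Y = Wm.t() * col;              // O x (Ho*Wo)
  arma::cube out(Ho, Wo, O);
  for (int o = 0; o < O; ++o)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        out(ho, wo, o) = Y(o, (size_t)ho + (size_t)Ho * wo) + b[o];
  return List::create(_["y"] = out, _["col"] = col);
}

// backward reusing the cached im2col matrix (identical arithmetic)
// [[Rcpp::export]]
List cpp_conv2d_bwd_cache(const arma::mat& col, int H, int W,
                          const NumericVector& w, const arma::cube& gy,
                          int stride, int pad, bool need_gx) {
  const int K = wdim(w, 0), C = wdim(w, 2), O = wdim(w, 3);
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::mat gY(O, (size_t)Ho * Wo);
  for (int o = 0; o < O; ++o)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        gY(o, (size_t)ho + (size_t)Ho * wo) = gy(ho, wo, o);
  const arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, O, false, true);
  arma::mat gW = col * gY.t();             // (K*K*C) x O
  arma::cube gx(need_gx ? H : 1, need_gx ? W : 1, need_gx ? C : 1,
                arma::fill::zeros);
  if (need_gx) {
    arma::mat gcol = Wm * gY;              // (K*K*C) x (Ho*Wo)
    col2im_add(gx, gcol, K, stride, pad, Ho, Wo);
  }
  NumericVector gw(w.size());
  std::copy(gW.begin(), gW.end(), gw.begin());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(O);
  for (int o = 0; o < O; ++o) gb[o] = arma::accu(gY.row(o));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const NumericVector& w,
                    const arma::cube& gy, int stride, int pad,
                    bool need_gx = true) {
  const int K = wdim(w, 0), C = wdim(w, 2), O = wdim(w, 3);
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::mat gY(O, (size_t)Ho * Wo);
  for (int o = 0; o < O; ++o)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        gY(o, (size_t)ho + (size_t)Ho * wo) = gy(ho, wo, o);
  arma::mat col = im2col(x, K, stride, pad, Ho, Wo);
  const arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, O, false, true);
  arma::mat gW = col * gY.t();             // (K*K*C) x O
  arma::cube gx(need_gx ? x.n_rows : 1, need_gx ? x.n_cols : 1,
                need_gx ? C : 1, arma::fill::zeros);
  if (need_gx) {
    arma::mat gcol = Wm * gY;              // (K*K*C) x (Ho*Wo)
    col2im_add(gx, gcol, K, stride, pad, Ho, Wo);
  }
  NumericVector gw(w.size());
  std::copy(gW.begin(), gW.end(), gw.begin());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(O);
  for (int o = 0; o < O; ++o) gb[o] = arma::accu(gY.row(o));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------- deformable conv -------
// Bilinear read in integer-index space; positions outside [0,H-1]x[0,W-1]
// contribute zero (and receive no gradient).
static inline double dsample(const arma::cube& x, int c, double iy, double ix) {
  const int H = x.n_rows, W = x.n_cols;
  if (iy <= -1.0 || iy >= (double)H || ix <= -1.0 || ix >= (double)W) return 0.0;
  int y0 = (int)std::floor(iy), x0 = (int)std::floor(ix);
  double fy = iy - y0, fx = ix - x0;
  double v = 0.0;
  for (int dy = 0; dy <= 1; ++dy)
    for (int dx = 0; dx <= 1; ++dx) {
      int yy = y0 + dy, xx = x0 + dx;
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      double wgt = (dy ? fy : 1.0 - fy) * (dx ? fx : 1.0 - fx);
      v += wgt * x(yy, xx, c);
    }
  return v;
}

// offsets cube: Ho x Wo x (2*K*K); channel 2*l = dy, 2*l+1 = dx for kernel
// position l = ki + K*kj.
// [[Rcpp::export]]
arma::cube cpp_dconv2d_fwd(const arma::cube& x, const NumericVector& w,
                           const NumericVector& b, const arma::cube& offs,
                           int stride, int pad) {
  const int K = wdim(w, 0), C = wdim(w, 2), O = wdim(w, 3);
  const int Ho = (x.n_rows + 2 * pad - K) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - K) / stride + 1;
  if ((int)offs.n_slices != 2 * K * K) stop("dconv2d: offset channel mismatch");
  if ((int)offs.n_rows != Ho || (int)offs.n_cols != Wo)
    stop("dconv2d: offset spatial shape mismatch");
  arma::cube out(Ho, Wo, O, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int kj = 0; kj < K; ++kj)
        for (int ki = 0; ki < K; ++ki) {
          const int l = ki + K * kj;
          const double iy = ho * stride - pad + ki + offs(ho, wo, 2 * l);
          const double ix = wo * stride - pad + kj + offs(ho, wo, 2 * l + 1);
          for (int c = 0; c < C; ++c) {
            const double v = dsample(x, c, iy, ix);
            if (v == 0.0) continue;
            for (int o = 0; o < O; ++o)
              out(ho, wo, o) += w[ki + K * (kj + K * (c + C * o))] * v;
          }
        }
  for (int o = 0; o < O; ++o) out.slice(o) += b[o];
  return out;
}

// [[Rcpp::export]]
List cpp_dconv2d_bwd(const arma::cube& x, const NumericVector& w,
                     const arma::cube& offs, const arma::cube& gy,
                     int stride, int pad) {
  const int K = wdim(w, 0), C = wdim(w, 2), O = wdim(w, 3);
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  arma::cube goffs(Ho, Wo, 2 * K * K, arma::fill::zeros);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(O);
  for (int o = 0; o < O; ++o) gb[o] = arma::accu(gy.slice(o));
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int kj = 0; kj < K; ++kj)
        for (int ki = 0; ki < K; ++ki) {
          const int l = ki + K * kj;
          const double iy = ho * stride - pad + ki + offs(ho, wo, 2 * l);
          const double ix = wo * stride - pad + kj + offs(ho, wo, 2 * l + 1);
          if (iy <= -1.0 || iy >= (double)H || ix <= -1.0 || ix >= (double)W)
            continue;
          const int y0 = (int)std::floor(iy), x0 = (int)std::floor(ix);
          const double fy = iy - y0, fx = ix - x0;
          for (int c = 0; c < C; ++c) {
            // upstream sensitivity of the sampled value for channel c
            double gv = 0.0;
            for (int o = 0; o < O; ++o)
              gv += gy(ho, wo, o) * w[ki + K * (kj + K * (c + C * o))];
            // value + its derivatives wrt iy, ix
            double v = 0.0, dvy = 0.0, dvx = 0.0;
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                int yy = y0 + dy, xx = x0 + dx;
                if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
                const double wy = dy ? fy : 1.0 - fy;
                const double wx = dx ? fx : 1.0 - fx;
                const double xv = x(yy, xx, c);
                v += wy * wx * xv;
                dvy += (dy ? 1.0 : -1.0) * wx * xv;
                dvx += (dx ? 1.0 : -1.0) * wy * xv;
                gx(yy, xx, c) += gv * wy * wx;
              }
            for (int o = 0; o < O; ++o)
              gw[ki + K * (kj + K * (c + C * o))] += gy(ho, wo, o) * v;
            goffs(ho, wo, 2 * l) += gv * dvy;
            goffs(ho, wo, 2 * l + 1) += gv * dvx;
          }
        }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb,
                      _["goffs"] = goffs);
}

// -------------------------------------------- bilinear 2x up / avgpool ------
// align_corners = FALSE convention; border replicated.
// [[Rcpp::export]]
arma::cube cpp_upsample2x_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int i = 0; i < 2 * H; ++i) {
    double ty = (i + 0.5) / 2.0 - 0.5;
    ty = std::min(std::max(ty, 0.0), (double)(H - 1));
    const int y0 = (int)std::floor(ty);
    const int y1 = std::min(y0 + 1, H - 1);
    const double fy = ty - y0;
    for (int j = 0; j < 2 * W; ++j) {
      double tx = (j + 0.5) / 2.0 - 0.5;
      tx = std::min(std::max(tx, 0.0), (double)(W - 1));
      const int x0 = (int)std::floor(tx);
      const int x1 = std::min(x0 + 1, W - 1);
      const double fx = tx - x0;
      for (int c = 0; c < C; ++c)
        out(i, j, c) = (1 - fy) * ((1 - fx) * x(y0, x0, c) + fx * x(y0, x1, c)) +
                       fy * ((1 - fx) * x(y1, x0, c) + fx * x(y1, x1, c));
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2x_bwd(const arma::cube& gy, int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int i = 0; i < (int)gy.n_rows; ++i) {
    double ty = (i + 0.5) / 2.0 - 0.5;
    ty = std::min(std::max(ty, 0.0), (double)(H - 1));
    const int y0 = (int)std::floor(ty);
    const int y1 = std::min(y0 + 1, H - 1);
    const double fy = ty - y0;
    for (int j = 0; j < (int)gy.n_cols; ++j) {
      double tx = (j + 0.5) / 2.0 - 0.5;
      tx = std::min(std::max(tx, 0.0), (double)(W - 1));
      const int x0 = (int)std::floor(tx);
      const int x1 = std::min(x0 + 1, W - 1);
      const double fx = tx - x0;
      for (int c = 0; c < C; ++c) {
        const double g = gy(i, j, c);
        gx(y0, x0, c) += g * (1 - fy) * (1 - fx);
        gx(y0, x1, c) += g * (1 - fy) * fx;
        gx(y1, x0, c) += g * fy * (1 - fx);
        gx(y1, x1, c) += g * fy * fx;
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  arma::cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                               x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows * 2, W = gy.n_cols * 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)gy.n_cols; ++j)
      for (int i = 0; i < (int)gy.n_rows; ++i) {
        const double g = 0.25 * gy(i, j, c);
        gx(2 * i, 2 * j, c) = g;
        gx(2 * i + 1, 2 * j, c) = g;
        gx(2 * i, 2 * j + 1, c) = g;
        gx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return gx;
}

// ------------------------------------------------------------- ROIAlign -----
// Continuous coordinates: pixel j spans [j, j+1), centre j + 0.5.  Sampling
// positions are clamped to the valid centre range (border replicate), so an
// ROI that exactly covers an integer-aligned region with one sample per bin
// reads pixel centres and reproduces the crop.
static inline double csample(const arma::cube& f, int c, double u, double v) {
  // u = y continuous coord, v = x continuous coord
  const int H = f.n_rows, W = f.n_cols;
  double ty = std::min(std::max(u - 0.5, 0.0), (double)(H - 1));
  double tx = std::min(std::max(v - 0.5, 0.0), (double)(W - 1));
  const int y0 = (int)std::floor(ty), x0 = (int)std::floor(tx);
  const int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
  const double fy = ty - y0, fx = tx - x0;
  return (1 - fy) * ((1 - fx) * f(y0, x0, c) + fx * f(y0, x1, c)) +
         fy * ((1 - fx) * f(y1, x0, c) + fx * f(y1, x1, c));
}

// [[Rcpp::export]]
arma::cube cpp_roi_align_fwd(const arma::cube& f, NumericVector roi,
                             int out_h, int out_w, int sampling_ratio) {
  const int C = f.n_slices;
  const double x0 = roi[0], y0 = roi[1], x1 = roi[2], y1 = roi[3];
  const double bh = (y1 - y0) / out_h, bw = (x1 - x0) / out_w;
  int ny = sampling_ratio > 0 ? sampling_ratio : std::max(1, (int)std::ceil(bh));
  int nx = sampling_ratio > 0 ? sampling_ratio : std::max(1, (int)std::ceil(bw));
  arma::cube out(out_h, out_w, C, arma::fill::zeros);
  for (int i = 0; i < out_h; ++i)
    for (int j = 0; j < out_w; ++j) {
      for (int sy = 0; sy < ny; ++sy)
        for (int sx = 0; sx < nx; ++sx) {
          const double u = y0 + (i + (sy + 0.5) / ny) * bh;
          const double v = x0 + (j + (sx + 0.5) / nx) * bw;
          for (int c = 0; c < C; ++c) out(i, j, c) += csample(f, c, u, v);
        }
      for (int c = 0; c < C; ++c) out(i, j, c) /= (double)(ny * nx);
    }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_roi_align_bwd(const arma::cube& gy, NumericVector roi,
                             int H, int W, int C, int sampling_ratio) {
  const int out_h = gy.n_rows, out_w = gy.n_cols;
  const double x0 = roi[0], y0 = roi[1], x1 = roi[2], y1 = roi[3];
  const double bh = (y1 - y0) / out_h, bw = (x1 - x0) / out_w;
  int ny = sampling_ratio > 0 ? sampling_ratio : std::max(1, (int)std::ceil(bh));
  int nx = sampling_ratio > 0 ? sampling_ratio : std::max(1, (int)std::ceil(bw));
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int i = 0; i < out_h; ++i)
    for (int j = 0; j < out_w; ++j)
      for (int sy = 0; sy < ny; ++sy)
        for (int sx = 0; sx < nx; ++sx) {
          double ty = std::min(std::max(y0 + (i + (sy + 0.5) / ny) * bh - 0.5, 0.0),
                               (double)(H - 1));
          double tx = std::min(std::max(x0 + (j + (sx + 0.5) / nx) * bw - 0.5, 0.0),
                               (double)(W - 1));
          const int yy0 = (int)std::floor(ty), xx0 = (int)std::floor(tx);
          const int yy1 = std::min(yy0 + 1, H - 1), xx1 = std::min(xx0 + 1, W - 1);
          const double fy = ty - yy0, fx = tx - xx0;
          for (int c = 0; c < C; ++c) {
            const double g = gy(i, j, c) / (double)(ny * nx);
            gx(yy0, xx0, c) += g * (1 - fy) * (1 - fx);
            gx(yy0, xx1, c) += g * (1 - fy) * fx;
            gx(yy1, xx0, c) += g * fy * (1 - fx);
            gx(yy1, xx1, c) += g * fy * fx;
          }
        }
  return gx;
}

// --------------------------------------------------------- point sample -----
// points: N x 2 matrix of normalised (u, v) in [0,1]^2, u = x-fraction,
// v = y-fraction; returns N x C matrix of bilinear reads at (u*W, v*H).
// [[Rcpp::export]]
arma::mat cpp_point_sample_fwd(const arma::cube& f, const arma::mat& pts) {
  const int N = pts.n_rows, C = f.n_slices;
  arma::mat out(N, C);
  for (int n = 0; n < N; ++n) {
    const double v = pts(n, 0) * f.n_cols;  // x coord
    const double u = pts(n, 1) * f.n_rows;  // y coord
    for (int c = 0; c < C; ++c) out(n, c) = csample(f, c, u, v);
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_point_sample_bwd(const arma::mat& gy, const arma::mat& pts,
                                int H, int W, int C) {
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int n = 0; n < (int)pts.n_rows; ++n) {
    double tx = std::min(std::max(pts(n, 0) * W - 0.5, 0.0), (double)(W - 1));
    double ty = std::min(std::max(pts(n, 1) * H - 0.5, 0.0), (double)(H - 1));
    const int y0 = (int)std::floor(ty), x0 = (int)std::floor(tx);
    const int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
    const double fy = ty - y0, fx = tx - x0;
    for (int c = 0; c < C; ++c) {
      const double g = gy(n, c);
      gx(y0, x0, c) += g * (1 - fy) * (1 - fx);
      gx(y0, x1, c) += g * (1 - fy) * fx;
      gx(y1, x0, c) += g * fy * (1 - fx);
      gx(y1, x1, c) += g * fy * fx;
    }
  }
  return gx;
}

// ------------------------------------------------- polygon rasterisation ----
// Even-odd scanline fill of a polygon whose vertices lie on the integer pixel
// grid (as produced by boundary tracing along pixel edges).  A pixel belongs
// to the mask iff its centre (x+0.5, y+0.5) is inside.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_polygon(NumericVector xs, NumericVector ys,
                                    int H, int W) {
  LogicalMatrix out(H, W);
  const int n = xs.size();
  std::vector<double> cross;
  for (int row = 0; row < H; ++row) {
    const double yc = row + 0.5;
    cross.clear();
    for (int e = 0; e < n; ++e) {
      const double y1 = ys[e], y2 = ys[(e + 1) % n];
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        const double x1 = xs[e], x2 = xs[(e + 1) % n];
        cross.push_back(x1 + (yc - y1) / (y2 - y1) * (x2 - x1));
      }
    }
    std::sort(cross.begin(), cross.end());
    for (size_t k = 0; k + 1 < cross.size(); k += 2) {
      int a = (int)std::ceil(cross[k] - 0.5);
      int b = (int)std::floor(cross[k + 1] - 0.5);
      a = std::max(a, 0);
      b = std::min(b, W - 1);
      for (int col = a; col <= b; ++col) out(row, col) = true;
    }
  }
  return out;
}

// --------------------------------------------------------------- box IoU ----
// Pairwise IoU between boxes given as (x, y, w, h) rows.
// [[Rcpp::export]]
arma::mat cpp_box_iou(const arma::mat& a, const arma::mat& b) {
  arma::mat out(a.n_rows, b.n_rows);
  for (size_t i = 0; i < a.n_rows; ++i) {
    const double ax0 = a(i, 0), ay0 = a(i, 1);
    const double ax1 = ax0 + a(i, 2), ay1 = ay0 + a(i, 3);
    const double aa = a(i, 2) * a(i, 3);
    for (size_t j = 0; j < b.n_rows; ++j) {
      const double ix = std::max(0.0, std::min(ax1, b(j, 0) + b(j, 2)) -
                                          std::max(ax0, b(j, 0)));
      const double iy = std::max(0.0, std::min(ay1, b(j, 1) + b(j, 3)) -
                                          std::max(ay0, b(j, 1)));
      const double inter = ix * iy;
      const double uni = aa + b(j, 2) * b(j, 3) - inter;
      out(i, j) = uni > 0 ? inter / uni : 0.0;
    }
  }
  return out;
}

// ------------------------------------------------------------ group norm ----
// [[Rcpp::export]]
List cpp_groupnorm_fwd(const arma::cube& x, const arma::vec& gamma,
                       const arma::vec& beta, int groups, double eps) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (groups > C) groups = C;
  const int gsz = C / groups;
  arma::cube y(H, W, C), xhat(H, W, C);
  arma::vec invstd(groups), mu(groups);
  for (int g = 0; g < groups; ++g) {
    const int c0 = g * gsz;
    const int c1 = (g == groups - 1) ? C - 1 : (g + 1) * gsz - 1;
    const arma::cube sub = x.slices(c0, c1);
    const double m = arma::accu(sub) / sub.n_elem;
    double v = 0.0;
    for (arma::uword i = 0; i < sub.n_elem; ++i) {
      const double d = sub(i) - m;
      v += d * d;
    }
    v /= sub.n_elem;
    const double is = 1.0 / std::sqrt(v + eps);
    mu(g) = m;
    invstd(g) = is;
    for (int c = c0; c <= c1; ++c) {
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double xh = (x(i, j, c) - m) * is;
          xhat(i, j, c) = xh;
          y(i, j, c) = xh * gamma(c) + beta(c);
        }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_groupnorm_bwd(const arma::cube& gr, const arma::cube& xhat,
                       const arma::vec& invstd, const arma::vec& gamma,
                       int groups) {
  const int H = gr.n_rows, W = gr.n_cols, C = gr.n_slices;
  if (groups > C) groups = C;
  const int gsz = C / groups;
  arma::vec ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        sg += gr(i, j, c) * xhat(i, j, c);
        sb += gr(i, j, c);
      }
    ggamma(c) = sg;
    gbeta(c) = sb;
  }
  arma::cube gx(H, W, C);
  for (int g = 0; g < groups; ++g) {
    const int c0 = g * gsz;
    const int c1 = (g == groups - 1) ? C - 1 : (g + 1) * gsz - 1;
    const double n = (double)(c1 - c0 + 1) * H * W;
    double s1 = 0.0, s2 = 0.0;
    for (int c = c0; c <= c1; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double dh = gr(i, j, c) * gamma(c);
          s1 += dh;
          s2 += dh * xhat(i, j, c);
        }
    const double is = invstd(g);
    for (int c = c0; c <= c1; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double dh = gr(i, j, c) * gamma(c);
          gx(i, j, c) = is / n * (n * dh - s1 - xhat(i, j, c) * s2);
        }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}
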
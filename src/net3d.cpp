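#include <Rcpp.h>
using namespace Rcpp;

// 3D convolution kernels for (D, H, W, C) column-major arrays.
// Zero padding `pad` = (pd, ph, pw) is applied on both sides of each spatial
// axis; stride is 1. Weights are (kd, kh, kw, Cin, Cout); one bias per output
// channel. Output spatial dim = in + 2*pad - k + 1.

static inline R_xlen_t idx4(int d, int h, int w, int c, int D, int H, int W) {
  return (R_xlen_t)d + (R_xlen_t)D * (h + (R_xlen_t)H * (w + (R_xlen_t)W * c));
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector wt, NumericVector b,
                            IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Ci = wd[3], Co = wd[4];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = D + 2 * pd - kd + 1, Ho = H + 2 * ph - kh + 1, Wo = W + 2 * pw - kw + 1;
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("convolution output dimension < 1");
  NumericVector y((R_xlen_t)Do * Ho * Wo * Co);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co);
  const double *X = x.begin();
  const double *Wt = wt.begin();
  double *Y = y.begin();
  // bias fill
  for (int co = 0; co < Co; ++co) {
    double *yc = Y + (R_xlen_t)Do * Ho * Wo * co;
    std::fill(yc, yc + (R_xlen_t)Do * Ho * Wo, b[co]);
  }
  // per kernel offset, accumulate a shifted copy of x (contiguous inner loop)
  for (int co = 0; co < Co; ++co) {
    for (int ci = 0; ci < Ci; ++ci) {
      for (int w_ = 0; w_ < kw; ++w_) {
        const int ow0 = std::max(0, pw - w_), ow1 = std::min(Wo - 1, W - 1 + pw - w_);
        for (int h_ = 0; h_ < kh; ++h_) {
          const int oh0 = std::max(0, ph - h_), oh1 = std::min(Ho - 1, H - 1 + ph - h_);
          for (int d_ = 0; d_ < kd; ++d_) {
            const int od0 = std::max(0, pd - d_), od1 = std::min(Do - 1, D - 1 + pd - d_);
            if (od1 < od0 || oh1 < oh0 || ow1 < ow0) continue;
            const double wv = Wt[(R_xlen_t)d_ + (R_xlen_t)kd * (h_ + (R_xlen_t)kh * (w_ + (R_xlen_t)kw * (ci + (R_xlen_t)Ci * co)))];
            const int len = od1 - od0 + 1;
            for (int ow = ow0; ow <= ow1; ++ow) {
              const int iw = ow + w_ - pw;
              for (int oh = oh0; oh <= oh1; ++oh) {
                const int ih = oh + h_ - ph;
                double *yp = Y + idx4(od0, oh, ow, co, Do, Ho, Wo);
                const double *xp = X + idx4(od0 + d_ - pd, ih, iw, ci, D, H, W);
                for (int t = 0; t < len; ++t) yp[t] += wv * xp[t];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// Returns list(dx, dw, db) for upstream gradient dy.
// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector wt, IntegerVector pad,
                   NumericVector dy, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Ci = wd[3], Co = wd[4];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = yd[0], Ho = yd[1], Wo = yd[2];
  NumericVector dx((R_xlen_t)D * H * W * Ci);
  dx.attr("dim") = IntegerVector::create(D, H, W, Ci);
  NumericVector dw(wt.size());
  dw.attr("dim") = wd;
  NumericVector db(Co);
  const double *X = x.begin();
  const double *Wt = wt.begin();
  const double *DY = dy.begin();
  double *DX = dx.begin();
  double *DW = dw.begin();
  // The upstream gradient is sparse after max-pool backward (one nonzero
  // per pooling window), so iterate output positions and skip zeros.
  for (int co = 0; co < Co; ++co) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        for (int od = 0; od < Do; ++od) {
          const double g = DY[idx4(od, oh, ow, co, Do, Ho, Wo)];
          if (g == 0.0) continue;
          db[co] += g;
          for (int ci = 0; ci < Ci; ++ci) {
            for (int w_ = 0; w_ < kw; ++w_) {
              const int iw = ow + w_ - pw;
              if (iw < 0 || iw >= W) continue;
              for (int h_ = 0; h_ < kh; ++h_) {
                const int ih = oh + h_ - ph;
                if (ih < 0 || ih >= H) continue;
                for (int d_ = 0; d_ < kd; ++d_) {
                  const int id = od + d_ - pd;
                  if (id < 0 || id >= D) continue;
                  const R_xlen_t xi = idx4(id, ih, iw, ci, D, H, W);
                  const R_xlen_t wi = (R_xlen_t)d_ + (R_xlen_t)kd * (h_ + (R_xlen_t)kh * (w_ + (R_xlen_t)kw * (ci + (R_xlen_t)Ci * co)));
                  DW[wi] += g * X[xi];
                  if (need_dx) DX[xi] += g * Wt[wi];
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Ceil-mode non-overlapping max pooling: output dim = ceil(in / pool), the
// last window along an axis may be partial. Returns the pooled array and the
// 1-based linear index (into x) of each selected maximum, for the backward
// pass. Ties resolve to the first voxel in scan order.
// [[Rcpp::export]]
List cpp_maxpool3d_fw(NumericVector x, IntegerVector pool) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int pd = pool[0], ph = pool[1], pw = pool[2];
  const int Do = (D + pd - 1) / pd, Ho = (H + ph - 1) / ph, Wo = (W + pw - 1) / pw;
  NumericVector y((R_xlen_t)Do * Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  IntegerVector am(y.size());
  const double *X = x.begin();
  double *Y = y.begin();
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < Wo; ++ow) {
      const int w0 = ow * pw, w1 = std::min(w0 + pw, W);
      for (int oh = 0; oh < Ho; ++oh) {
        const int h0 = oh * ph, h1 = std::min(h0 + ph, H);
        for (int od = 0; od < Do; ++od) {
          const int d0 = od * pd, d1 = std::min(d0 + pd, D);
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int iw = w0; iw < w1; ++iw)
            for (int ih = h0; ih < h1; ++ih)
              for (int id = d0; id < d1; ++id) {
                const R_xlen_t xi = idx4(id, ih, iw, c, D, H, W);
                if (X[xi] > best) { best = X[xi]; besti = xi; }
              }
          const R_xlen_t yi = idx4(od, oh, ow, c, Do, Ho, Wo);
          Y[yi] = best;
          am[yi] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bw(IntegerVector argmax, NumericVector dy,
                               IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[argmax[i] - 1] += dy[i];
  return dx;
}
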
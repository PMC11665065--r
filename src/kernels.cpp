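// Dense CNN kernels for nucseg.
//
// Tensor layout: R arrays with dim c(N, C, H, W), column-major, so the
// flat index of (n, c, h, w) (all 0-based) is n + N*(c + C*(h + H*w)).
// All kernels are single-threaded and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline R_xlen_t idx4(R_xlen_t n, R_xlen_t c, R_xlen_t h, R_xlen_t w,
                            R_xlen_t N, R_xlen_t C, R_xlen_t H) {
  return n + N * (c + C * (h + H * w));
}

// ---------------------------------------------------------------- conv2d ---

// im2col: columns indexed by m = n + N*(ho + Ho*wo); rows by
// k = c + C*(ki + KH*kj), matching the weight layout (O, C, KH, KW).
static arma::mat im2col(const double *px, int N, int C, int H, int W,
                        int KH, int KW, int Ho, int Wo, int stride, int pad) {
  arma::mat col(C * KH * KW, (arma::uword)N * Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int n = 0; n < N; ++n) {
        arma::uword m = n + (arma::uword)N * (ho + (arma::uword)Ho * wo);
        double *cm = col.colptr(m);
        for (int kj = 0; kj < KW; ++kj) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < KH; ++ki) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            const double *xs = px + idx4(n, 0, hi, wi, N, C, H);
            double *cs = cm + (ki + KH * kj) * C;
            for (int c = 0; c < C; ++c) cs[c] = xs[(R_xlen_t)N * c];
          }
        }
      }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int O = wd[0], KH = wd[2], KW = wd[3];
  int Ho = (H + 2 * pad - KH) / stride + 1;
  int Wo = (W + 2 * pad - KW) / stride + 1;
  // weights (O, C, KH, KW) -> matrix (K x O): element (k, o) = w(o, k)
  arma::mat wm(C * KH * KW, O);
  const double *pw = w.begin();
  for (int o = 0; o < O; ++o)
    for (int k = 0; k < C * KH * KW; ++k)
      wm(k, o) = pw[o + (R_xlen_t)O * k];
  arma::mat col = im2col(x.begin(), N, C, H, W, KH, KW, Ho, Wo, stride, pad);
  arma::mat ym = wm.t() * col;  // (O x M)
  NumericVector y(static_cast<R_xlen_t>(N) * O * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, O, Ho, Wo);
  double *py = y.begin();
  const double *pb = b.begin();
  bool has_b = b.size() == O;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int n = 0; n < N; ++n) {
        arma::uword m = n + (arma::uword)N * (ho + (arma::uword)Ho * wo);
        const double *yc = ym.colptr(m);
        for (int o = 0; o < O; ++o)
          py[idx4(n, o, ho, wo, N, O, Ho)] = yc[o] + (has_b ? pb[o] : 0.0);
      }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int O = wd[0], KH = wd[2], KW = wd[3];
  int Ho = gd[2], Wo = gd[3];
  int K = C * KH * KW;
  arma::mat wm(K, O);
  const double *pw = w.begin();
  for (int o = 0; o < O; ++o)
    for (int k = 0; k < K; ++k) wm(k, o) = pw[o + (R_xlen_t)O * k];
  // gy -> (O x M)
  arma::mat gym(O, (arma::uword)N * Ho * Wo);
  const double *pg = gy.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int n = 0; n < N; ++n) {
        arma::uword m = n + (arma::uword)N * (ho + (arma::uword)Ho * wo);
        double *gc = gym.colptr(m);
        for (int o = 0; o < O; ++o)
          gc[o] = pg[idx4(n, o, ho, wo, N, O, Ho)];
      }
  arma::mat col = im2col(x.begin(), N, C, H, W, KH, KW, Ho, Wo, stride, pad);
  arma::mat gwm = gym * col.t();        // (O x K)
  arma::mat gcol = wm * gym;            // (K x M)
  NumericVector gx(x.size()), gw(w.size()), gb(O);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  double *pgw = gw.begin();
  for (int o = 0; o < O; ++o)
    for (int k = 0; k < K; ++k) pgw[o + (R_xlen_t)O * k] = gwm(o, k);
  arma::vec gbv = arma::sum(gym, 1);
  for (int o = 0; o < O; ++o) gb[o] = gbv(o);
  // col2im scatter-add
  double *pgx = gx.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int n = 0; n < N; ++n) {
        arma::uword m = n + (arma::uword)N * (ho + (arma::uword)Ho * wo);
        const double *cm = gcol.colptr(m);
        for (int kj = 0; kj < KW; ++kj) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < KH; ++ki) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            double *xs = pgx + idx4(n, 0, hi, wi, N, C, H);
            const double *cs = cm + (ki + KH * kj) * C;
            for (int c = 0; c < C; ++c) xs[(R_xlen_t)N * c] += cs[c];
          }
        }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------- deformable conv2d ---
//
// Sampling point for output (ho, wo), kernel tap (ki, kj):
//   y = ho*stride - pad + ki*dilation + off_y,  x likewise.
// Offsets are stored (dy, dx) interleaved per tap, row-major over the grid:
// channel 2*k holds dy and 2*k+1 holds dx for tap k = ki*KW + kj.
// Out-of-bounds samples contribute zero (zero padding in the bilinear sum).

static inline double bilin(const double *px, int n, int c, double y, double x,
                           int N, int C, int H, int W) {
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  double wy1 = y - y0, wx1 = x - x0;
  double v = 0.0;
  for (int dy = 0; dy <= 1; ++dy) {
    int yy = y0 + dy;
    if (yy < 0 || yy >= H) continue;
    double wy = dy ? wy1 : 1.0 - wy1;
    if (wy == 0.0) continue;
    for (int dx = 0; dx <= 1; ++dx) {
      int xx = x0 + dx;
      if (xx < 0 || xx >= W) continue;
      double wx = dx ? wx1 : 1.0 - wx1;
      if (wx == 0.0) continue;
      v += wy * wx * px[idx4(n, c, yy, xx, N, C, H)];
    }
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_dconv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                              NumericVector off, int stride, int pad, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = off.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int O = wd[0], KH = wd[2], KW = wd[3];
  int Ho = od[2], Wo = od[3];
  NumericVector y(static_cast<R_xlen_t>(N) * O * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, O, Ho, Wo);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin(), *po = off.begin();
  double *py = y.begin();
  bool has_b = b.size() == O;
  int K2 = 2 * KH * KW;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int n = 0; n < N; ++n) {
        for (int o = 0; o < O; ++o)
          py[idx4(n, o, ho, wo, N, O, Ho)] = has_b ? pb[o] : 0.0;
        for (int ki = 0; ki < KH; ++ki)
          for (int kj = 0; kj < KW; ++kj) {
            int k = ki * KW + kj;
            double sy = ho * stride - pad + ki * dilation +
                        po[idx4(n, 2 * k, ho, wo, N, K2, Ho)];
            double sx = wo * stride - pad + kj * dilation +
                        po[idx4(n, 2 * k + 1, ho, wo, N, K2, Ho)];
            for (int c = 0; c < C; ++c) {
              double v = bilin(px, n, c, sy, sx, N, C, H, W);
              if (v == 0.0) continue;
              for (int o = 0; o < O; ++o)
                py[idx4(n, o, ho, wo, N, O, Ho)] +=
                    pw[o + (R_xlen_t)O * (c + (R_xlen_t)C * (ki + (R_xlen_t)KH * kj))] * v;
            }
          }
      }
  return y;
}

// [[Rcpp::export]]
List cpp_dconv2d_bwd(NumericVector x, NumericVector w, NumericVector off,
                     NumericVector gy, int stride, int pad, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = off.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int O = wd[0], KH = wd[2], KW = wd[3];
  int Ho = od[2], Wo = od[3];
  NumericVector gx(x.size()), gw(w.size()), gb(O), goff(off.size());
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  goff.attr("dim") = od;
  const double *px = x.begin(), *pw = w.begin(), *po = off.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin(), *pgo = goff.begin();
  int K2 = 2 * KH * KW;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int n = 0; n < N; ++n) {
        for (int o = 0; o < O; ++o)
          pgb[o] += pg[idx4(n, o, ho, wo, N, O, Ho)];
        for (int ki = 0; ki < KH; ++ki)
          for (int kj = 0; kj < KW; ++kj) {
            int k = ki * KW + kj;
            double sy = ho * stride - pad + ki * dilation +
                        po[idx4(n, 2 * k, ho, wo, N, K2, Ho)];
            double sx = wo * stride - pad + kj * dilation +
                        po[idx4(n, 2 * k + 1, ho, wo, N, K2, Ho)];
            int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
            double wy1 = sy - y0, wx1 = sx - x0;
            double g_sy = 0.0, g_sx = 0.0;
            for (int c = 0; c < C; ++c) {
              // dL/d(sampled value of channel c at this tap)
              double gv = 0.0;
              for (int o = 0; o < O; ++o)
                gv += pg[idx4(n, o, ho, wo, N, O, Ho)] *
                      pw[o + (R_xlen_t)O * (c + (R_xlen_t)C * (ki + (R_xlen_t)KH * kj))];
              double v = 0.0;
              for (int dy = 0; dy <= 1; ++dy) {
                int yy = y0 + dy;
                if (yy < 0 || yy >= H) continue;
                double wyv = dy ? wy1 : 1.0 - wy1;
                double sgn_y = dy ? 1.0 : -1.0;
                for (int dx = 0; dx <= 1; ++dx) {
                  int xx = x0 + dx;
                  if (xx < 0 || xx >= W) continue;
                  double wxv = dx ? wx1 : 1.0 - wx1;
                  double sgn_x = dx ? 1.0 : -1.0;
                  double xv = px[idx4(n, c, yy, xx, N, C, H)];
                  v += wyv * wxv * xv;
                  pgx[idx4(n, c, yy, xx, N, C, H)] += gv * wyv * wxv;
                  g_sy += gv * sgn_y * wxv * xv;
                  g_sx += gv * wyv * sgn_x * xv;
                }
              }
              for (int o = 0; o < O; ++o)
                pgw[o + (R_xlen_t)O * (c + (R_xlen_t)C * (ki + (R_xlen_t)KH * kj))] +=
                    pg[idx4(n, o, ho, wo, N, O, Ho)] * v;
            }
            pgo[idx4(n, 2 * k, ho, wo, N, K2, Ho)] += g_sy;
            pgo[idx4(n, 2 * k + 1, ho, wo, N, K2, Ho)] += g_sx;
          }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb, _["goff"] = goff);
}

// -------------------------------------------------------------- maxpool ---

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(N) * C * Ho * Wo);
  IntegerVector am(y.size());  // flat index into x of the max element
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = am.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t best_i = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              R_xlen_t ii = idx4(n, c, hi, wi, N, C, H);
              if (px[ii] > best) { best = px[ii]; best_i = ii; }
            }
          }
          R_xlen_t oi = idx4(n, c, ho, wo, N, C, Ho);
          py[oi] = best_i >= 0 ? best : 0.0;
          pa[oi] = (int)best_i;
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector argmax, IntegerVector xdim) {
  R_xlen_t sz = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(sz);
  gx.attr("dim") = xdim;
  const double *pg = gy.begin();
  const int *pa = argmax.begin();
  double *pgx = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (pa[i] >= 0) pgx[pa[i]] += pg[i];
  return gx;
}

// ------------------------------------------------------ bilinear resize ---
// Half-pixel mapping with edge clamping: src = (dst + 0.5) * (in/out) - 0.5.

// [[Rcpp::export]]
NumericVector cpp_resize_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y(static_cast<R_xlen_t>(N) * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  const double *px = x.begin();
  double *py = y.begin();
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int wo = 0; wo < Wo; ++wo) {
    double sx = (wo + 0.5) * sw - 0.5;
    if (sx < 0) sx = 0; if (sx > W - 1) sx = W - 1;
    int x0 = (int)std::floor(sx), x1 = x0 + 1 < W ? x0 + 1 : x0;
    double wx1 = sx - x0;
    for (int ho = 0; ho < Ho; ++ho) {
      double sy = (ho + 0.5) * sh - 0.5;
      if (sy < 0) sy = 0; if (sy > H - 1) sy = H - 1;
      int y0 = (int)std::floor(sy), y1 = y0 + 1 < H ? y0 + 1 : y0;
      double wy1 = sy - y0;
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          py[idx4(n, c, ho, wo, N, C, Ho)] =
              (1 - wy1) * (1 - wx1) * px[idx4(n, c, y0, x0, N, C, H)] +
              (1 - wy1) * wx1       * px[idx4(n, c, y0, x1, N, C, H)] +
              wy1 * (1 - wx1)       * px[idx4(n, c, y1, x0, N, C, H)] +
              wy1 * wx1             * px[idx4(n, c, y1, x1, N, C, H)];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bwd(NumericVector gy, IntegerVector xdim) {
  IntegerVector gd = gy.attr("dim");
  int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  int Ho = gd[2], Wo = gd[3];
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = xdim;
  const double *pg = gy.begin();
  double *pgx = gx.begin();
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int wo = 0; wo < Wo; ++wo) {
    double sx = (wo + 0.5) * sw - 0.5;
    if (sx < 0) sx = 0; if (sx > W - 1) sx = W - 1;
    int x0 = (int)std::floor(sx), x1 = x0 + 1 < W ? x0 + 1 : x0;
    double wx1 = sx - x0;
    for (int ho = 0; ho < Ho; ++ho) {
      double sy = (ho + 0.5) * sh - 0.5;
      if (sy < 0) sy = 0; if (sy > H - 1) sy = H - 1;
      int y0 = (int)std::floor(sy), y1 = y0 + 1 < H ? y0 + 1 : y0;
      double wy1 = sy - y0;
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double g = pg[idx4(n, c, ho, wo, N, C, Ho)];
          if (g == 0.0) continue;
          pgx[idx4(n, c, y0, x0, N, C, H)] += (1 - wy1) * (1 - wx1) * g;
          pgx[idx4(n, c, y0, x1, N, C, H)] += (1 - wy1) * wx1 * g;
          pgx[idx4(n, c, y1, x0, N, C, H)] += wy1 * (1 - wx1) * g;
          pgx[idx4(n, c, y1, x1, N, C, H)] += wy1 * wx1 * g;
        }
    }
  }
  return gx;
}
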
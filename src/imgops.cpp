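// Low-level raster operations: bicubic resampling, separable Gaussian
// smoothing, and z-buffered forward warps used by the synthetic renderer.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Catmull-Rom cubic convolution kernel (a = -0.5), support [-2, 2].
static inline double cubic_w(double x) {
  x = std::fabs(x);
  if (x < 1.0) return ((1.5 * x - 2.5) * x) * x + 1.0;
  if (x < 2.0) return ((-0.5 * x + 2.5) * x - 4.0) * x + 2.0;
  return 0.0;
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static double sample_bicubic(const NumericMatrix& img, double v, double u) {
  const int h = img.nrow(), w = img.ncol();
  const int r0 = (int)std::floor(v), c0 = (int)std::floor(u);
  double acc = 0.0, wsum = 0.0;
  for (int dr = -1; dr <= 2; ++dr) {
    const double wr = cubic_w(v - (r0 + dr));
    if (wr == 0.0) continue;
    const int rr = clampi(r0 + dr, 0, h - 1);
    for (int dc = -1; dc <= 2; ++dc) {
      const double wc = cubic_w(u - (c0 + dc));
      if (wc == 0.0) continue;
      const int cc = clampi(c0 + dc, 0, w - 1);
      acc += wr * wc * img(rr, cc);
      wsum += wr * wc;
    }
  }
  return acc / wsum;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bicubic(const NumericMatrix& src, int out_h, int out_w,
                                 double clip_lo, double clip_hi) {
  const int h = src.nrow(), w = src.ncol();
  NumericMatrix out(out_h, out_w);
  const double sy = (double)h / out_h, sx = (double)w / out_w;
  for (int c = 0; c < out_w; ++c) {
    const double u = (c + 0.5) * sx - 0.5;
    for (int r = 0; r < out_h; ++r) {
      const double v = (r + 0.5) * sy - 0.5;
      double val = sample_bicubic(src, v, u);
      if (val < clip_lo) val = clip_lo;
      if (val > clip_hi) val = clip_hi;
      out(r, c) = val;
    }
  }
  return out;
}

// Vectorised bicubic point sampling; u = 0-based column, v = 0-based row.
// [[Rcpp::export]]
NumericVector cpp_interp_bicubic(const NumericMatrix& img, const NumericVector& u,
                                 const NumericVector& v) {
  const int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_bicubic(img, v[i], u[i]);
  return out;
}

// Separable Gaussian blur, reflected borders.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& src, double sigma) {
  const int h = src.nrow(), w = src.ncol();
  if (sigma <= 0) return clone(src);
  int rad = (int)std::ceil(3.5 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& x : k) x /= s;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i;
      if (i >= n) i = 2 * n - 2 - i;
    }
    return i;
  };
  NumericMatrix tmp(h, w), out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * src(r, reflect(c + i, w));
      tmp(r, c) = acc;
    }
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * tmp(reflect(r + i, h), c);
      out(r, c) = acc;
    }
  return out;
}

// Rectified-stereo row warp: the second camera is the first translated by
// `baseline` along +X, so a surface point seen at column u1 in the reference
// view appears at u2 = u1 - fku*baseline/Z(u1) on the same row.  Rendering is
// a per-row forward march with a z-buffer (nearer surface wins), sampling the
// reference-view texture at sub-pixel positions along the row.
// [[Rcpp::export]]
List cpp_row_warp(const List& textures, const NumericMatrix& Z, double fku_b,
                  int substep) {
  const int h = Z.nrow(), w = Z.ncol();
  const int nt = textures.size();
  std::vector<NumericMatrix> tex(nt), outs(nt);
  for (int t = 0; t < nt; ++t) {
    tex[t] = as<NumericMatrix>(textures[t]);
    outs[t] = NumericMatrix(h, w);
  }
  NumericMatrix z2(h, w);
  NumericMatrix off(h, w);   // writer's distance to the pixel centre
  LogicalMatrix filled(h, w);
  std::fill(z2.begin(), z2.end(), R_PosInf);
  std::fill(off.begin(), off.end(), R_PosInf);
  const double du = 1.0 / substep;
  const double zeps = 0.5;   // depth tie window: z-buffer only resolves
                             // genuine occlusions, not sub-pixel jitter
  for (int r = 0; r < h; ++r) {
    for (double u1 = 0.0; u1 <= w - 1 + 1e-9; u1 += du) {
      // linear interp of depth along the row
      int c0 = (int)std::floor(u1);
      int c1 = std::min(c0 + 1, w - 1);
      double f = u1 - c0;
      double z = (1.0 - f) * Z(r, c0) + f * Z(r, c1);
      double u2 = u1 - fku_b / z;
      int cdst = (int)std::lround(u2);
      if (cdst < 0 || cdst >= w) continue;
      double o = std::fabs(u2 - cdst);
      bool take = !filled(r, cdst) || z < z2(r, cdst) - zeps ||
                  (z < z2(r, cdst) + zeps && o < off(r, cdst));
      if (take) {
        z2(r, cdst) = z;
        off(r, cdst) = o;
        filled(r, cdst) = true;
        for (int t = 0; t < nt; ++t)
          outs[t](r, cdst) = (1.0 - f) * tex[t](r, c0) + f * tex[t](r, c1);
      }
    }
    // fill unseen edge/occlusion columns from nearest rendered neighbour in row
    int last = -1;
    for (int c = 0; c < w; ++c) if (filled(r, c)) { last = c; break; }
    if (last < 0) continue;
    for (int c = 0; c < w; ++c) {
      if (filled(r, c)) { last = c; continue; }
      // look ahead for the nearest filled column on the right
      int rgt = -1;
      for (int c2 = c + 1; c2 < w; ++c2) if (filled(r, c2)) { rgt = c2; break; }
      int src = (rgt >= 0 && (last < 0 || rgt - c < c - last)) ? rgt : last;
      z2(r, c) = z2(r, src);
      for (int t = 0; t < nt; ++t) outs[t](r, c) = outs[t](r, src);
    }
  }
  List ot(nt);
  for (int t = 0; t < nt; ++t) ot[t] = outs[t];
  return List::create(_["textures"] = ot, _["depth"] = z2, _["filled"] = filled);
}

// General 2-D forward warp with z-buffer, used by the turntable (rotation)
// renderer: each supersampled source pixel is mapped through precomputed
// target coordinates (map_u, map_v, in target pixels, 0-based) and splatted
// onto the nearest target pixel; the nearer surface wins.  Holes left by
// expansion are filled from the nearest filled pixel in the same row.
// [[Rcpp::export]]
List cpp_forward_warp2d(const List& textures, const NumericMatrix& Zcam,
                        const NumericMatrix& map_u, const NumericMatrix& map_v,
                        int out_h, int out_w, int supersample) {
  const int h = Zcam.nrow(), w = Zcam.ncol();
  const int nt = textures.size();
  std::vector<NumericMatrix> tex(nt), outs(nt);
  for (int t = 0; t < nt; ++t) {
    tex[t] = as<NumericMatrix>(textures[t]);
    outs[t] = NumericMatrix(out_h, out_w);
  }
  NumericMatrix z2(out_h, out_w);
  NumericMatrix off(out_h, out_w);
  LogicalMatrix filled(out_h, out_w);
  std::fill(z2.begin(), z2.end(), R_PosInf);
  std::fill(off.begin(), off.end(), R_PosInf);
  const double zeps = 0.5;
  const double step = 1.0 / supersample;
  auto bil = [&](const NumericMatrix& m, double rr, double cc) {
    int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
    int r1 = std::min(r0 + 1, h - 1), c1 = std::min(c0 + 1, w - 1);
    double fr = rr - r0, fc = cc - c0;
    return (1 - fr) * ((1 - fc) * m(r0, c0) + fc * m(r0, c1)) +
           fr * ((1 - fc) * m(r1, c0) + fc * m(r1, c1));
  };
  for (double rr = 0.0; rr <= h - 1 + 1e-9; rr += step) {
    for (double cc = 0.0; cc <= w - 1 + 1e-9; cc += step) {
      double z = bil(Zcam, rr, cc);
      double ut = bil(map_u, rr, cc), vt = bil(map_v, rr, cc);
      int cd = (int)std::lround(ut), rd = (int)std::lround(vt);
      if (cd < 0 || cd >= out_w || rd < 0 || rd >= out_h) continue;
      double o = (ut - cd) * (ut - cd) + (vt - rd) * (vt - rd);
      bool take = !filled(rd, cd) || z < z2(rd, cd) - zeps ||
                  (z < z2(rd, cd) + zeps && o < off(rd, cd));
      if (take) {
        z2(rd, cd) = z;
        off(rd, cd) = o;
        filled(rd, cd) = true;
        for (int t = 0; t < nt; ++t) outs[t](rd, cd) = bil(tex[t], rr, cc);
      }
    }
  }
  for (int r = 0; r < out_h; ++r) {
    int last = -1;
    for (int c = 0; c < out_w; ++c) if (filled(r, c)) { last = c; break; }
    if (last < 0) continue;
    for (int c = 0; c < out_w; ++c) {
      if (filled(r, c)) { last = c; continue; }
      int rgt = -1;
      for (int c2 = c + 1; c2 < out_w; ++c2) if (filled(r, c2)) { rgt = c2; break; }
      int src = (rgt >= 0 && (last < 0 || rgt - c < c - last)) ? rgt : last;
      z2(r, c) = z2(r, src);
      for (int t = 0; t < nt; ++t) outs[t](r, c) = outs[t](r, src);
    }
  }
  List ot(nt);
  for (int t = 0; t < nt; ++t) ot[t] = outs[t];
  return List::create(_["textures"] = ot, _["depth"] = z2, _["filled"] = filled);
}
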
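// Scale-invariant feature transform: Gaussian scale-space pyramid,
// difference-of-Gaussian extrema with quadratic subpixel refinement,
// contrast and edge-response rejection, 36-bin orientation assignment and
// the 4x4x8 gradient-histogram descriptor.  Follows the standard Lowe
// formulation; images enter as doubles in [0, 1].
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

constexpr int    N_LAYERS    = 3;      // DoG layers searched per octave
constexpr double SIGMA0      = 1.6;    // base scale of each octave
constexpr double CONTRAST_TH = 0.04;   // Lowe contrast threshold
constexpr double EDGE_TH     = 10.0;   // principal-curvature ratio limit
constexpr int    IMG_BORDER  = 5;
constexpr int    MAX_INTERP  = 5;
constexpr int    DESC_D      = 4;      // descriptor spatial bins
constexpr int    DESC_N      = 8;      // descriptor orientation bins
constexpr int    ORI_BINS    = 36;
constexpr double ORI_SIG_FCT = 1.5;
constexpr double ORI_RADIUS  = 3.0 * ORI_SIG_FCT;
constexpr double ORI_PEAK    = 0.8;
constexpr double DESC_SCL    = 3.0;
constexpr double DESC_MAG_TH = 0.2;

struct FImg {
  int h = 0, w = 0;
  std::vector<float> d;
  FImg() {}
  FImg(int h_, int w_) : h(h_), w(w_), d((size_t)h_ * w_) {}
  inline float at(int r, int c) const { return d[(size_t)r * w + c]; }
  inline float& at(int r, int c) { return d[(size_t)r * w + c]; }
};

struct Kp {
  double r, c;        // position in base-image pixels
  double size;        // diameter in base-image pixels
  double angle;       // degrees
  double response;
  int octave, layer;
  double scl_octv;    // scale within its octave (pixels of that octave)
  int ri, ci;         // integer position within the octave image
};

void gauss_blur(const FImg& src, FImg& dst, double sigma) {
  const int h = src.h, w = src.w;
  dst = FImg(h, w);
  if (sigma <= 0) { dst.d = src.d; return; }
  int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<float> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = (float)std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto& x : k) x = (float)(x / s);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i; if (i >= n) i = 2 * n - 2 - i; }
    return i;
  };
  FImg tmp(h, w);
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      float acc = 0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * src.at(r, refl(c + i, w));
      tmp.at(r, c) = acc;
    }
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      float acc = 0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * tmp.at(refl(r + i, h), c);
      dst.at(r, c) = acc;
    }
}

FImg downsample2(const FImg& src) {
  FImg out(src.h / 2, src.w / 2);
  for (int r = 0; r < out.h; ++r)
    for (int c = 0; c < out.w; ++c) out.at(r, c) = src.at(2 * r, 2 * c);
  return out;
}

FImg upsample2_bilinear(const FImg& src) {
  FImg out(src.h * 2, src.w * 2);
  for (int r = 0; r < out.h; ++r) {
    double sr = std::min((double)src.h - 1, r * 0.5);
    int r0 = (int)sr, r1 = std::min(r0 + 1, src.h - 1);
    double fr = sr - r0;
    for (int c = 0; c < out.w; ++c) {
      double sc = std::min((double)src.w - 1, c * 0.5);
      int c0 = (int)sc, c1 = std::min(c0 + 1, src.w - 1);
      double fc = sc - c0;
      out.at(r, c) = (float)((1 - fr) * ((1 - fc) * src.at(r0, c0) + fc * src.at(r0, c1)) +
                             fr * ((1 - fc) * src.at(r1, c0) + fc * src.at(r1, c1)));
    }
  }
  return out;
}

// Quadratic refinement of an extremum; returns true if the keypoint survives.
bool adjust_extremum(const std::vector<FImg>& dog, int& layer, int& r, int& c,
                     double& xr, double& xc, double& xl, double& contrast) {
  const int h = dog[0].h, w = dog[0].w;
  for (int iter = 0; iter < MAX_INTERP; ++iter) {
    const FImg& D0 = dog[layer - 1];
    const FImg& D1 = dog[layer];
    const FImg& D2 = dog[layer + 1];
    double dx = 0.5 * (D1.at(r, c + 1) - D1.at(r, c - 1));
    double dy = 0.5 * (D1.at(r + 1, c) - D1.at(r - 1, c));
    double ds = 0.5 * (D2.at(r, c) - D0.at(r, c));
    double v2 = 2.0 * D1.at(r, c);
    double dxx = D1.at(r, c + 1) + D1.at(r, c - 1) - v2;
    double dyy = D1.at(r + 1, c) + D1.at(r - 1, c) - v2;
    double dss = D2.at(r, c) + D0.at(r, c) - v2;
    double dxy = 0.25 * (D1.at(r + 1, c + 1) - D1.at(r + 1, c - 1) -
                         D1.at(r - 1, c + 1) + D1.at(r - 1, c - 1));
    double dxs = 0.25 * (D2.at(r, c + 1) - D2.at(r, c - 1) -
                         D0.at(r, c + 1) + D0.at(r, c - 1));
    double dys = 0.25 * (D2.at(r + 1, c) - D2.at(r - 1, c) -
                         D0.at(r + 1, c) + D0.at(r - 1, c));
    // solve H x = -g for the 3x3 Hessian (Cramer)
    double det = dxx * (dyy * dss - dys * dys) - dxy * (dxy * dss - dys * dxs) +
                 dxs * (dxy * dys - dyy * dxs);
    if (std::fabs(det) < 1e-30) return false;
    double bx = -dx, by = -dy, bs = -ds;
    xc = (bx * (dyy * dss - dys * dys) - dxy * (by * dss - dys * bs) +
          dxs * (by * dys - dyy * bs)) / det;
    xr = (dxx * (by * dss - dys * bs) - bx * (dxy * dss - dys * dxs) +
          dxs * (dxy * bs - by * dxs)) / det;
    xl = (dxx * (dyy * bs - by * dys) - dxy * (dxy * bs - by * dxs) +
          bx * (dxy * dys - dyy * dxs)) / det;
    if (std::fabs(xr) < 0.5 && std::fabs(xc) < 0.5 && std::fabs(xl) < 0.5) {
      contrast = D1.at(r, c) + 0.5 * (dx * xc + dy * xr + ds * xl);
      return std::fabs(contrast) >= CONTRAST_TH / N_LAYERS;
    }
    c += (int)std::lround(xc);
    r += (int)std::lround(xr);
    layer += (int)std::lround(xl);
    if (layer < 1 || layer > N_LAYERS || c < IMG_BORDER || c >= w - IMG_BORDER ||
        r < IMG_BORDER || r >= h - IMG_BORDER)
      return false;
  }
  return false;
}

bool edge_ok(const FImg& D, int r, int c) {
  double v2 = 2.0 * D.at(r, c);
  double dxx = D.at(r, c + 1) + D.at(r, c - 1) - v2;
  double dyy = D.at(r + 1, c) + D.at(r - 1, c) - v2;
  double dxy = 0.25 * (D.at(r + 1, c + 1) - D.at(r + 1, c - 1) -
                       D.at(r - 1, c + 1) + D.at(r - 1, c - 1));
  double tr = dxx + dyy, det = dxx * dyy - dxy * dxy;
  if (det <= 0) return false;
  return tr * tr * EDGE_TH < (EDGE_TH + 1) * (EDGE_TH + 1) * det;
}

// Orientation histogram around (r, c); returns dominant-peak magnitude and
// fills `hist` (smoothed, circular).
double ori_hist(const FImg& img, int r, int c, int radius, double sigma,
                std::vector<double>& hist) {
  hist.assign(ORI_BINS, 0.0);
  std::vector<double> raw(ORI_BINS, 0.0);
  const double expf = -0.5 / (sigma * sigma);
  for (int i = -radius; i <= radius; ++i) {
    int y = r + i;
    if (y <= 0 || y >= img.h - 1) continue;
    for (int j = -radius; j <= radius; ++j) {
      int x = c + j;
      if (x <= 0 || x >= img.w - 1) continue;
      double dx = img.at(y, x + 1) - img.at(y, x - 1);
      double dy = img.at(y - 1, x) - img.at(y + 1, x);
      double mag = std::sqrt(dx * dx + dy * dy);
      double ang = std::atan2(dy, dx) * 180.0 / M_PI;
      if (ang < 0) ang += 360.0;
      double wgt = std::exp((i * i + j * j) * expf);
      int bin = (int)std::lround(ang * ORI_BINS / 360.0) % ORI_BINS;
      raw[bin] += wgt * mag;
    }
  }
  double mx = 0;
  for (int i = 0; i < ORI_BINS; ++i) {
    int im2 = (i - 2 + ORI_BINS) % ORI_BINS, im1 = (i - 1 + ORI_BINS) % ORI_BINS;
    int ip1 = (i + 1) % ORI_BINS, ip2 = (i + 2) % ORI_BINS;
    hist[i] = (raw[im2] + raw[ip2]) / 16.0 + 4.0 * (raw[im1] + raw[ip1]) / 16.0 +
              6.0 * raw[i] / 16.0;
    mx = std::max(mx, hist[i]);
  }
  return mx;
}

void calc_descriptor(const FImg& img, double r, double c, double ori,
                     double scl, float* dst) {
  const int d = DESC_D, n = DESC_N;
  const double cos_t0 = std::cos(ori * M_PI / 180.0);
  const double sin_t0 = std::sin(ori * M_PI / 180.0);
  const double bins_per_rad = n / 360.0;
  const double exp_scale = -1.0 / (d * d * 0.5);
  const double hist_width = DESC_SCL * scl;
  int radius = (int)std::lround(hist_width * M_SQRT2 * (d + 1) * 0.5);
  radius = std::min(radius, (int)std::sqrt((double)img.h * img.h + (double)img.w * img.w));
  const double cos_t = cos_t0 / hist_width, sin_t = sin_t0 / hist_width;
  const int ri = (int)std::lround(r), ci = (int)std::lround(c);
  std::vector<double> hist((d + 2) * (d + 2) * (n + 2), 0.0);
  for (int i = -radius; i <= radius; ++i) {
    for (int j = -radius; j <= radius; ++j) {
      double c_rot = j * cos_t - i * sin_t;
      double r_rot = j * sin_t + i * cos_t;
      double rbin = r_rot + d / 2 - 0.5;
      double cbin = c_rot + d / 2 - 0.5;
      int y = ri + i, x = ci + j;
      if (rbin > -1 && rbin < d && cbin > -1 && cbin < d &&
          y > 0 && y < img.h - 1 && x > 0 && x < img.w - 1) {
        double dx = img.at(y, x + 1) - img.at(y, x - 1);
        double dy = img.at(y - 1, x) - img.at(y + 1, x);
        double ang = std::atan2(dy, dx) * 180.0 / M_PI;
        if (ang < 0) ang += 360.0;
        double obin = (ang - ori) * bins_per_rad;
        double mag = std::sqrt(dx * dx + dy * dy) *
                     std::exp((c_rot * c_rot + r_rot * r_rot) * exp_scale);
        int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin),
            o0 = (int)std::floor(obin);
        rbin -= r0; cbin -= c0; obin -= o0;
        if (o0 < 0) o0 += n;
        if (o0 >= n) o0 -= n;
        // trilinear spreading over 8 neighbouring bins
        double v_r1 = mag * rbin, v_r0 = mag - v_r1;
        double v_rc11 = v_r1 * cbin, v_rc10 = v_r1 - v_rc11;
        double v_rc01 = v_r0 * cbin, v_rc00 = v_r0 - v_rc01;
        double v111 = v_rc11 * obin, v110 = v_rc11 - v111;
        double v101 = v_rc10 * obin, v100 = v_rc10 - v101;
        double v011 = v_rc01 * obin, v010 = v_rc01 - v011;
        double v001 = v_rc00 * obin, v000 = v_rc00 - v001;
        size_t idx = (size_t)((r0 + 1) * (d + 2) + (c0 + 1)) * (n + 2) + o0;
        hist[idx] += v000;
        hist[idx + 1] += v001;
        hist[idx + (n + 2)] += v010;
        hist[idx + (n + 3)] += v011;
        hist[idx + (d + 2) * (n + 2)] += v100;
        hist[idx + (d + 2) * (n + 2) + 1] += v101;
        hist[idx + (d + 3) * (n + 2)] += v110;
        hist[idx + (d + 3) * (n + 2) + 1] += v111;
      }
    }
  }
  // fold the circular orientation bins and copy out
  std::vector<double> out(d * d * n);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) {
      size_t idx = (size_t)((i + 1) * (d + 2) + (j + 1)) * (n + 2);
      hist[idx] += hist[idx + n];
      hist[idx + 1] += hist[idx + n + 1];
      for (int k = 0; k < n; ++k) out[(i * d + j) * n + k] = hist[idx + k];
    }
  double nrm2 = 0;
  for (double v : out) nrm2 += v * v;
  double thr = std::sqrt(nrm2) * DESC_MAG_TH;
  nrm2 = 0;
  for (double& v : out) { if (v > thr) v = thr; nrm2 += v * v; }
  double fac = 512.0 / std::max(std::sqrt(nrm2), 1e-12);
  for (int k = 0; k < d * d * n; ++k)
    dst[k] = (float)std::min(255.0, out[k] * fac);
}

}  // namespace

// [[Rcpp::export]]
List cpp_sift(const NumericMatrix& image, int nfeatures, bool double_image) {
  FImg base0(image.nrow(), image.ncol());
  for (int r = 0; r < base0.h; ++r)
    for (int c = 0; c < base0.w; ++c) base0.at(r, c) = (float)image(r, c);
  const double first_scale = double_image ? 0.5 : 1.0;
  FImg base = double_image ? upsample2_bilinear(base0) : base0;
  const double init_sigma = double_image ? 1.0 : 0.5;  // assumed capture blur
  {
    double s = std::sqrt(std::max(SIGMA0 * SIGMA0 - init_sigma * init_sigma, 0.01));
    FImg b;
    gauss_blur(base, b, s);
    base = b;
  }
  int n_oct = (int)std::floor(std::log2((double)std::min(base.h, base.w))) - 3;
  n_oct = std::max(1, std::min(n_oct, 8));

  // per-octave incremental blur amounts
  std::vector<double> sig(N_LAYERS + 3);
  sig[0] = SIGMA0;
  for (int i = 1; i < N_LAYERS + 3; ++i) {
    double prev = SIGMA0 * std::pow(2.0, (i - 1) / (double)N_LAYERS);
    double tot = SIGMA0 * std::pow(2.0, i / (double)N_LAYERS);
    sig[i] = std::sqrt(tot * tot - prev * prev);
  }

  std::vector<Kp> kps;
  std::vector<std::vector<FImg>> gauss_keep(n_oct);
  FImg oct_base = base;
  for (int o = 0; o < n_oct; ++o) {
    std::vector<FImg> g(N_LAYERS + 3);
    g[0] = oct_base;
    for (int i = 1; i < N_LAYERS + 3; ++i) gauss_blur(g[i - 1], g[i], sig[i]);
    std::vector<FImg> dog(N_LAYERS + 2);
    for (int i = 0; i < N_LAYERS + 2; ++i) {
      dog[i] = FImg(g[i].h, g[i].w);
      for (size_t k = 0; k < dog[i].d.size(); ++k)
        dog[i].d[k] = g[i + 1].d[k] - g[i].d[k];
    }
    const int h = g[0].h, w = g[0].w;
    const double prelim = 0.5 * CONTRAST_TH / N_LAYERS;
    for (int layer = 1; layer <= N_LAYERS; ++layer) {
      const FImg& D0 = dog[layer - 1];
      const FImg& D1 = dog[layer];
      const FImg& D2 = dog[layer + 1];
      for (int r = IMG_BORDER; r < h - IMG_BORDER; ++r) {
        for (int c = IMG_BORDER; c < w - IMG_BORDER; ++c) {
          float v = D1.at(r, c);
          if (std::fabs(v) <= prelim) continue;
          bool is_max = true, is_min = true;
          for (int dr = -1; dr <= 1 && (is_max || is_min); ++dr)
            for (int dc = -1; dc <= 1 && (is_max || is_min); ++dc) {
              float a = D0.at(r + dr, c + dc);
              float b = D1.at(r + dr, c + dc);
              float e = D2.at(r + dr, c + dc);
              if (dr == 0 && dc == 0) {
                if (v < a || v < e) is_max = false;
                if (v > a || v > e) is_min = false;
              } else {
                float mx = std::max(std::max(a, b), e);
                float mn = std::min(std::min(a, b), e);
                if (v < mx) is_max = false;
                if (v > mn) is_min = false;
              }
            }
          if (!(is_max && v > 0) && !(is_min && v < 0)) continue;
          int rr = r, cc = c, ll = layer;
          double xr, xc, xl, contr;
          if (!adjust_extremum(dog, ll, rr, cc, xr, xc, xl, contr)) continue;
          if (!edge_ok(dog[ll], rr, cc)) continue;
          Kp kp;
          double oct_mult = std::pow(2.0, o) * first_scale;
          kp.r = (rr + xr) * oct_mult;
          kp.c = (cc + xc) * oct_mult;
          kp.scl_octv = SIGMA0 * std::pow(2.0, (ll + xl) / (double)N_LAYERS);
          kp.size = kp.scl_octv * 2.0 * oct_mult;
          kp.response = std::fabs(contr);
          kp.octave = o;
          kp.layer = ll;
          kp.ri = rr;
          kp.ci = cc;
          kp.angle = -1;
          kps.push_back(kp);
        }
      }
    }
    gauss_keep[o] = std::move(g);
    if (o + 1 < n_oct) oct_base = downsample2(gauss_keep[o][N_LAYERS]);
  }

  // orientation assignment (may split a keypoint into several orientations)
  std::vector<Kp> oriented;
  std::vector<double> hist;
  for (const Kp& kp : kps) {
    const FImg& img = gauss_keep[kp.octave][kp.layer];
    int radius = (int)std::lround(ORI_RADIUS * kp.scl_octv);
    double mx = ori_hist(img, kp.ri, kp.ci, radius, ORI_SIG_FCT * kp.scl_octv, hist);
    double thr = mx * ORI_PEAK;
    for (int i = 0; i < ORI_BINS; ++i) {
      int l = (i - 1 + ORI_BINS) % ORI_BINS, rgt = (i + 1) % ORI_BINS;
      if (hist[i] > hist[l] && hist[i] > hist[rgt] && hist[i] >= thr) {
        double bin = i + 0.5 * (hist[l] - hist[rgt]) /
                             (hist[l] - 2 * hist[i] + hist[rgt]);
        if (bin < 0) bin += ORI_BINS;
        if (bin >= ORI_BINS) bin -= ORI_BINS;
        Kp k2 = kp;
        k2.angle = 360.0 - bin * (360.0 / ORI_BINS);
        if (std::fabs(k2.angle - 360.0) < 1e-6) k2.angle = 0.0;
        oriented.push_back(k2);
      }
    }
  }

  // deduplicate, order strongest-first (stable tie-break on position)
  std::sort(oriented.begin(), oriented.end(), [](const Kp& a, const Kp& b) {
    if (a.response != b.response) return a.response > b.response;
    if (a.r != b.r) return a.r < b.r;
    if (a.c != b.c) return a.c < b.c;
    return a.angle < b.angle;
  });
  oriented.erase(std::unique(oriented.begin(), oriented.end(),
                             [](const Kp& a, const Kp& b) {
                               return a.r == b.r && a.c == b.c &&
                                      a.size == b.size && a.angle == b.angle;
                             }),
                 oriented.end());
  if (nfeatures > 0 && (int)oriented.size() > nfeatures) oriented.resize(nfeatures);

  const int n = (int)oriented.size();
  NumericMatrix pts(n, 6);
  NumericMatrix desc(n, DESC_D * DESC_D * DESC_N);
  std::vector<float> buf(DESC_D * DESC_D * DESC_N);
  for (int i = 0; i < n; ++i) {
    const Kp& kp = oriented[i];
    pts(i, 0) = kp.c;           // u (column)
    pts(i, 1) = kp.r;           // v (row)
    pts(i, 2) = kp.size;        // diameter
    pts(i, 3) = kp.angle;
    pts(i, 4) = kp.response;
    pts(i, 5) = kp.octave;
    double ang = 360.0 - kp.angle;
    if (std::fabs(ang - 360.0) < 1e-6) ang = 0.0;
    calc_descriptor(gauss_keep[kp.octave][kp.layer], kp.ri, kp.ci, ang,
                    kp.scl_octv, buf.data());
    for (int k = 0; k < DESC_D * DESC_D * DESC_N; ++k) desc(i, k) = buf[k];
  }
  colnames(pts) = CharacterVector::create("u", "v", "diameter", "angle",
                                          "response", "octave");
  return List::create(_["pts"] = pts, _["desc"] = desc);
}
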
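// Sparse-to-dense depth interpolation over the image plane: incremental
// Bowyer-Watson Delaunay triangulation of the sample locations, barycentric
// (piecewise-linear) rasterization inside the convex hull, and exact
// nearest-sample assignment (bucket grid) outside it.
#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tri { int a, b, c; double cx, cy, r2; };

void circumcircle(double ax, double ay, double bx, double by, double cx,
                  double cy, double& ox, double& oy, double& r2) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-12) { ox = oy = 0; r2 = 1e300; return; }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  ox = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - ox, dy = ay - oy;
  r2 = dx * dx + dy * dy;
}

std::vector<Tri> delaunay(const std::vector<double>& px,
                          const std::vector<double>& py) {
  const int n = (int)px.size();
  std::vector<double> x(px), y(py);
  double xmin = *std::min_element(x.begin(), x.end());
  double xmax = *std::max_element(x.begin(), x.end());
  double ymin = *std::min_element(y.begin(), y.end());
  double ymax = *std::max_element(y.begin(), y.end());
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  // super-triangle vertices appended after the real points
  x.push_back(midx - 30 * dmax); y.push_back(midy - dmax);
  x.push_back(midx + 30 * dmax); y.push_back(midy - dmax);
  x.push_back(midx);             y.push_back(midy + 30 * dmax);
  std::vector<Tri> tris;
  auto mk = [&](int a, int b, int c) {
    Tri t{a, b, c, 0, 0, 0};
    circumcircle(x[a], y[a], x[b], y[b], x[c], y[c], t.cx, t.cy, t.r2);
    return t;
  };
  tris.push_back(mk(n, n + 1, n + 2));
  for (int i = 0; i < n; ++i) {
    std::map<std::pair<int, int>, int> edge_count;
    std::vector<Tri> keep;
    std::vector<std::pair<int, int>> boundary;
    for (const Tri& t : tris) {
      double dx = px[i] - t.cx, dy = py[i] - t.cy;
      if (dx * dx + dy * dy <= t.r2 * (1.0 + 1e-12)) {
        auto add = [&](int a, int b) {
          auto key = std::minmax(a, b);
          edge_count[{key.first, key.second}]++;
        };
        add(t.a, t.b); add(t.b, t.c); add(t.c, t.a);
      } else {
        keep.push_back(t);
      }
    }
    // edges seen once bound the cavity
    std::map<std::pair<int, int>, int> seen;
    for (const Tri& t : tris) {
      double dx = px[i] - t.cx, dy = py[i] - t.cy;
      if (dx * dx + dy * dy <= t.r2 * (1.0 + 1e-12)) {
        auto edge = [&](int a, int b) {
          auto key = std::minmax(a, b);
          if (edge_count[{key.first, key.second}] == 1)
            boundary.push_back({a, b});
        };
        edge(t.a, t.b); edge(t.b, t.c); edge(t.c, t.a);
      }
    }
    tris = std::move(keep);
    for (auto& e : boundary) tris.push_back(mk(e.first, e.second, i));
  }
  // drop triangles touching the super-triangle
  std::vector<Tri> out;
  for (const Tri& t : tris)
    if (t.a < n && t.b < n && t.c < n) out.push_back(t);
  return out;
}

}  // namespace

// u, v: 0-based pixel coordinates of samples; z: sample values; mask: pixels
// to fill.  method: 0 = nearest everywhere, 1 = linear inside the hull with
// nearest outside.  Returns a matrix with NA outside the mask.
// [[Rcpp::export]]
NumericMatrix cpp_densify(const NumericVector& u, const NumericVector& v,
                          const NumericVector& z, const LogicalMatrix& mask,
                          int method) {
  const int h = mask.nrow(), w = mask.ncol();
  NumericMatrix out(h, w);
  std::fill(out.begin(), out.end(), NA_REAL);
  // deduplicate identical sample locations (keep first)
  std::vector<double> px, py, pz;
  {
    std::map<std::pair<long long, long long>, bool> seen;
    for (int i = 0; i < u.size(); ++i) {
      auto key = std::make_pair((long long)std::llround(u[i] * 1024.0),
                                (long long)std::llround(v[i] * 1024.0));
      if (seen.count(key)) continue;
      seen[key] = true;
      px.push_back(u[i]); py.push_back(v[i]); pz.push_back(z[i]);
    }
  }
  const int n = (int)px.size();
  if (n == 0) return out;
  LogicalMatrix done(h, w);
  if (method == 1 && n >= 3) {
    std::vector<Tri> tris = delaunay(px, py);
    for (const Tri& t : tris) {
      double ax = px[t.a], ay = py[t.a], bx = px[t.b], by = py[t.b],
             cx = px[t.c], cy = py[t.c];
      double den = (by - cy) * (ax - cx) + (cx - bx) * (ay - cy);
      if (std::fabs(den) < 1e-12) continue;
      int c0 = std::max(0, (int)std::floor(std::min({ax, bx, cx})));
      int c1 = std::min(w - 1, (int)std::ceil(std::max({ax, bx, cx})));
      int r0 = std::max(0, (int)std::floor(std::min({ay, by, cy})));
      int r1 = std::min(h - 1, (int)std::ceil(std::max({ay, by, cy})));
      for (int r = r0; r <= r1; ++r)
        for (int c = c0; c <= c1; ++c) {
          if (!mask(r, c) || done(r, c)) continue;
          double l1 = ((by - cy) * (c - cx) + (cx - bx) * (r - cy)) / den;
          double l2 = ((cy - ay) * (c - cx) + (ax - cx) * (r - cy)) / den;
          double l3 = 1.0 - l1 - l2;
          const double eps = -1e-9;
          if (l1 >= eps && l2 >= eps && l3 >= eps) {
            out(r, c) = l1 * pz[t.a] + l2 * pz[t.b] + l3 * pz[t.c];
            done(r, c) = true;
          }
        }
    }
  }
  // nearest-sample fill for everything still empty (or method == 0)
  // bucket grid for exact nearest-neighbour queries
  double cell = std::max(1.0, std::sqrt((double)h * w / n));
  int gw = std::max(1, (int)std::ceil(w / cell));
  int gh = std::max(1, (int)std::ceil(h / cell));
  std::vector<std::vector<int>> buckets((size_t)gw * gh);
  auto bidx = [&](double uu, double vv) {
    int gc = std::min(gw - 1, std::max(0, (int)(uu / cell)));
    int gr = std::min(gh - 1, std::max(0, (int)(vv / cell)));
    return gr * gw + gc;
  };
  for (int i = 0; i < n; ++i) buckets[bidx(px[i], py[i])].push_back(i);
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      if (!mask(r, c) || done(r, c)) continue;
      int gc = std::min(gw - 1, std::max(0, (int)(c / cell)));
      int gr = std::min(gh - 1, std::max(0, (int)(r / cell)));
      double bestd = 1e300;
      int besti = -1;
      for (int ring = 0; ring < std::max(gw, gh); ++ring) {
        bool any = false;
        for (int dr = -ring; dr <= ring; ++dr)
          for (int dc = -ring; dc <= ring; ++dc) {
            if (std::max(std::abs(dr), std::abs(dc)) != ring) continue;
            int rr = gr + dr, cc = gc + dc;
            if (rr < 0 || rr >= gh || cc < 0 || cc >= gw) continue;
            any = true;
            for (int i : buckets[(size_t)rr * gw + cc]) {
              double dx = px[i] - c, dy = py[i] - r;
              double d = dx * dx + dy * dy;
              if (d < bestd) { bestd = d; besti = i; }
            }
          }
        // a hit at ring k guarantees the true nearest lies within ring k+1
        if (besti >= 0 && ring >= 1 &&
            bestd <= (ring - 1) * (ring - 1) * cell * cell)
          break;
        if (!any && besti >= 0) break;
      }
      if (besti >= 0) out(r, c) = pz[besti];
    }
  return out;
}
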
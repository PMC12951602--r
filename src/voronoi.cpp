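// Periodic Voronoi tessellation used to initialize the tissue: the seed
// points are tiled 3x3, triangulated with an incremental Bowyer-Watson
// Delaunay construction, and the Voronoi mesh of the central image is read
// off as the dual (circumcentres of triangles incident to each central
// point, ordered counter-clockwise). Duplicate circumcentres arising from
// the tiling are merged by their base-point triple with a positional check.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tri {
  int a, b, c;
  double ccx, ccy, r2;
  bool alive;
};

bool circumcircle(double ax, double ay, double bx, double by, double cx,
                  double cy, double& ox, double& oy, double& r2) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-12) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  ox = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - ox, dy = ay - oy;
  r2 = dx * dx + dy * dy;
  return true;
}

}  // namespace

// [[Rcpp::export]]
List vm_periodic_voronoi(NumericVector px, NumericVector py, double Lx,
                         double Ly) {
  int n = px.size();
  std::vector<double> X, Y;
  X.reserve(9 * n + 3); Y.reserve(9 * n + 3);
  // image order: iy = -1,0,1 outer, ix = -1,0,1 inner; central image index 4
  for (int iy = -1; iy <= 1; ++iy)
    for (int ix = -1; ix <= 1; ++ix)
      for (int i = 0; i < n; ++i) {
        X.push_back(px[i] + ix * Lx);
        Y.push_back(py[i] + iy * Ly);
      }
  int n9 = (int)X.size();
  // super-triangle
  double cx = Lx / 2.0, cy = Ly / 2.0, M = 40.0 * std::max(Lx, Ly);
  X.push_back(cx - M); Y.push_back(cy - M);
  X.push_back(cx + M); Y.push_back(cy - M);
  X.push_back(cx);     Y.push_back(cy + M);

  std::vector<Tri> tris;
  {
    Tri t; t.a = n9; t.b = n9 + 1; t.c = n9 + 2; t.alive = true;
    circumcircle(X[t.a], Y[t.a], X[t.b], Y[t.b], X[t.c], Y[t.c],
                 t.ccx, t.ccy, t.r2);
    tris.push_back(t);
  }

  std::vector<int> bad;
  std::map<std::pair<int, int>, int> edge_count;
  for (int p = 0; p < n9; ++p) {
    bad.clear();
    for (size_t i = 0; i < tris.size(); ++i) {
      if (!tris[i].alive) continue;
      double dx = X[p] - tris[i].ccx, dy = Y[p] - tris[i].ccy;
      if (dx * dx + dy * dy < tris[i].r2 * (1.0 + 1e-12)) bad.push_back((int)i);
    }
    edge_count.clear();
    for (int bi : bad) {
      const Tri& t = tris[bi];
      int e[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
      for (auto& ed : e) {
        auto key = std::make_pair(std::min(ed[0], ed[1]),
                                  std::max(ed[0], ed[1]));
        edge_count[key]++;
      }
      tris[bi].alive = false;
    }
    for (auto& kv : edge_count) {
      if (kv.second != 1) continue;  // interior cavity edge
      int a = kv.first.first, b = kv.first.second;
      // orient CCW
      double cross = (X[b] - X[a]) * (Y[p] - Y[a]) -
                     (Y[b] - Y[a]) * (X[p] - X[a]);
      Tri t;
      if (cross > 0) { t.a = a; t.b = b; } else { t.a = b; t.b = a; }
      t.c = p;
      t.alive = circumcircle(X[t.a], Y[t.a], X[t.b], Y[t.b], X[t.c], Y[t.c],
                             t.ccx, t.ccy, t.r2);
      if (t.alive) tris.push_back(t);
    }
    // periodic compaction to keep the scan cheap
    if (tris.size() > 20000) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (const auto& t : tris) if (t.alive) keep.push_back(t);
      tris.swap(keep);
    }
  }

  // triangles incident to central-image points
  std::vector<std::vector<int>> incident(n);
  std::vector<int> kept;
  for (size_t i = 0; i < tris.size(); ++i) {
    const Tri& t = tris[i];
    if (!t.alive || t.a >= n9 || t.b >= n9 || t.c >= n9) continue;
    int ids[3] = {t.a, t.b, t.c};
    bool used = false;
    for (int id : ids)
      if (id / n == 4) { incident[id % n].push_back((int)i); used = true; }
    if (used) kept.push_back((int)i);
  }

  // canonical Voronoi vertices: merge triangle circumcentres by base triple
  std::map<std::array<int, 3>, std::vector<int>> canon;  // triple -> vert ids
  std::vector<double> wx, wy;   // wrapped vertex coords
  std::vector<int> tri_vert(tris.size(), -1);
  double tol = 1e-6 * std::max(Lx, Ly);
  for (int ti : kept) {
    const Tri& t = tris[ti];
    std::array<int, 3> key = {t.a % n, t.b % n, t.c % n};
    std::sort(key.begin(), key.end());
    double gx = t.ccx - Lx * std::floor(t.ccx / Lx);
    double gy = t.ccy - Ly * std::floor(t.ccy / Ly);
    int vid = -1;
    auto it = canon.find(key);
    if (it != canon.end()) {
      for (int cand : it->second) {
        double dx = gx - wx[cand]; dx -= Lx * std::nearbyint(dx / Lx);
        double dy = gy - wy[cand]; dy -= Ly * std::nearbyint(dy / Ly);
        if (dx * dx + dy * dy < tol * tol) { vid = cand; break; }
      }
    }
    if (vid < 0) {
      vid = (int)wx.size();
      wx.push_back(gx); wy.push_back(gy);
      canon[key].push_back(vid);
    }
    tri_vert[ti] = vid;
  }

  // build cell loops: incident circumcentres sorted CCW around the point
  List loops(n);
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& inc = incident[i];
    int k = (int)inc.size();
    if (k < 3) stop("degenerate Voronoi cell for point %d", i + 1);
    double pxi = px[i], pyi = py[i];
    std::vector<std::pair<double, int>> ang(k);
    for (int j = 0; j < k; ++j) {
      const Tri& t = tris[inc[j]];
      ang[j] = {std::atan2(t.ccy - pyi, t.ccx - pxi), tri_vert[inc[j]]};
    }
    std::sort(ang.begin(), ang.end());
    IntegerVector lp(k);
    for (int j = 0; j < k; ++j) lp[j] = ang[j].second + 1;
    loops[i] = lp;
  }

  return List::create(_["vx"] = NumericVector(wx.begin(), wx.end()),
                      _["vy"] = NumericVector(wy.begin(), wy.end()),
                      _["loops"] = loops);
}
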
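// Core vertex-model machinery: cell geometry under the periodic minimum-image
// metric, tissue energy, analytic vertex forces, overdamped Brownian Euler
// stepping with short-edge (T1 candidate) detection, and per-edge tensions.
//
// Conventions: cell loops are counter-clockwise; all per-cell geometry is
// computed on a locally unwrapped copy of the loop (consecutive vertices are
// assumed closer than half the box). Energies are in units of K_A * A0^2.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Mesh {
  int nv, nc;
  std::vector<double> x, y;
  std::vector<int> start;      // CSR offsets, length nc+1
  std::vector<int> verts;      // 0-based vertex ids
  double Lx, Ly;

  double wrapdx(double dx) const { return dx - Lx * std::nearbyint(dx / Lx); }
  double wrapdy(double dy) const { return dy - Ly * std::nearbyint(dy / Ly); }
};

struct Edge {
  int a, b;      // vertex ids, a < b
  int c1, c2;    // cell ids sharing the edge (-1 if absent)
  bool het;      // separates mesectoderm from ectoderm
};

Mesh build_mesh(const NumericVector& vx, const NumericVector& vy,
                const List& loops, double Lx, double Ly) {
  Mesh m;
  m.nv = vx.size();
  m.nc = loops.size();
  m.x.assign(vx.begin(), vx.end());
  m.y.assign(vy.begin(), vy.end());
  m.Lx = Lx; m.Ly = Ly;
  m.start.resize(m.nc + 1);
  m.start[0] = 0;
  for (int c = 0; c < m.nc; ++c) {
    IntegerVector lp = loops[c];
    m.start[c + 1] = m.start[c] + lp.size();
  }
  m.verts.resize(m.start[m.nc]);
  for (int c = 0; c < m.nc; ++c) {
    IntegerVector lp = loops[c];
    for (int j = 0; j < lp.size(); ++j) m.verts[m.start[c] + j] = lp[j] - 1;
  }
  return m;
}

// type coding: 0 = ectoderm_pre, 1 = ectoderm_post, 2 = mesectoderm
inline bool is_mesec(int t) { return t == 2; }

std::vector<Edge> build_edges(const Mesh& m, const IntegerVector& ctype) {
  std::unordered_map<long long, int> idx;
  std::vector<Edge> edges;
  idx.reserve(m.start[m.nc]);
  for (int c = 0; c < m.nc; ++c) {
    int n = m.start[c + 1] - m.start[c];
    for (int j = 0; j < n; ++j) {
      int a = m.verts[m.start[c] + j];
      int b = m.verts[m.start[c] + (j + 1) % n];
      long long key = (long long)std::min(a, b) * m.nv + std::max(a, b);
      auto it = idx.find(key);
      if (it == idx.end()) {
        Edge e; e.a = std::min(a, b); e.b = std::max(a, b);
        e.c1 = c; e.c2 = -1; e.het = false;
        idx[key] = (int)edges.size();
        edges.push_back(e);
      } else {
        edges[it->second].c2 = c;
      }
    }
  }
  for (auto& e : edges) {
    if (e.c2 >= 0)
      e.het = is_mesec(ctype[e.c1]) != is_mesec(ctype[e.c2]);
  }
  return edges;
}

// Unwrap a cell loop into buf (closed polygon, starting at its first vertex's
// wrapped position); returns number of vertices.
inline int unwrap_loop(const Mesh& m, int c, std::vector<double>& ux,
                       std::vector<double>& uy) {
  int s = m.start[c], n = m.start[c + 1] - s;
  ux.resize(n); uy.resize(n);
  ux[0] = m.x[m.verts[s]]; uy[0] = m.y[m.verts[s]];
  for (int j = 1; j < n; ++j) {
    int v = m.verts[s + j], w = m.verts[s + j - 1];
    ux[j] = ux[j - 1] + m.wrapdx(m.x[v] - m.x[w]);
    uy[j] = uy[j - 1] + m.wrapdy(m.y[v] - m.y[w]);
  }
  return n;
}

inline void cell_area_perim(const std::vector<double>& ux,
                            const std::vector<double>& uy, int n,
                            double& A, double& P) {
  A = 0.0; P = 0.0;
  for (int j = 0; j < n; ++j) {
    int k = (j + 1) % n;
    A += ux[j] * uy[k] - ux[k] * uy[j];
    double dx = ux[k] - ux[j], dy = uy[k] - uy[j];
    P += std::sqrt(dx * dx + dy * dy);
  }
  A *= 0.5;
}

// Accumulate -grad E (cell elastic terms) into fx, fy. Hot path: uses
// branch-based minimum-image wrapping (consecutive loop vertices are
// always closer than half the box) and one length evaluation per edge.
void add_cell_forces(const Mesh& m, const double* A0, const double* P0,
                     double KA, double KP, std::vector<double>& fx,
                     std::vector<double>& fy, std::vector<double>& ux,
                     std::vector<double>& uy, std::vector<double>& ex,
                     std::vector<double>& ey, std::vector<double>& il) {
  const double hx = 0.5 * m.Lx, hy = 0.5 * m.Ly;
  for (int c = 0; c < m.nc; ++c) {
    int s = m.start[c], n = m.start[c + 1] - s;
    if ((int)ux.size() < n) {
      ux.resize(n); uy.resize(n); ex.resize(n); ey.resize(n); il.resize(n);
    }
    ux[0] = m.x[m.verts[s]]; uy[0] = m.y[m.verts[s]];
    for (int j = 1; j < n; ++j) {
      double dx = m.x[m.verts[s + j]] - m.x[m.verts[s + j - 1]];
      double dy = m.y[m.verts[s + j]] - m.y[m.verts[s + j - 1]];
      if (dx > hx) dx -= m.Lx; else if (dx < -hx) dx += m.Lx;
      if (dy > hy) dy -= m.Ly; else if (dy < -hy) dy += m.Ly;
      ux[j] = ux[j - 1] + dx; uy[j] = uy[j - 1] + dy;
    }
    double A = 0.0, P = 0.0;
    for (int j = 0; j < n; ++j) {
      int k = j + 1 == n ? 0 : j + 1;
      A += ux[j] * uy[k] - ux[k] * uy[j];
      double dx = ux[k] - ux[j], dy = uy[k] - uy[j];
      double l = std::sqrt(dx * dx + dy * dy);
      double inv = l > 1e-14 ? 1.0 / l : 0.0;
      ex[j] = dx; ey[j] = dy; il[j] = inv;
      P += l;
    }
    A *= 0.5;
    double cA = 2.0 * KA * (A - A0[c]);
    double cP = 2.0 * KP * (P - P0[c]);
    for (int j = 0; j < n; ++j) {
      int jm = j == 0 ? n - 1 : j - 1;
      int jp = j + 1 == n ? 0 : j + 1;
      double dAx = 0.5 * (uy[jp] - uy[jm]);
      double dAy = 0.5 * (ux[jm] - ux[jp]);
      double dPx = ex[jm] * il[jm] - ex[j] * il[j];
      double dPy = ey[jm] * il[jm] - ey[j] * il[j];
      int v = m.verts[s + j];
      fx[v] -= cA * dAx + cP * dPx;
      fy[v] -= cA * dAy + cP * dPy;
    }
  }
}

void add_line_tension_forces(const Mesh& m, const std::vector<Edge>& edges,
                             double gamma, std::vector<double>& fx,
                             std::vector<double>& fy) {
  if (gamma == 0.0) return;
  for (const auto& e : edges) {
    if (!e.het) continue;
    double dx = m.wrapdx(m.x[e.b] - m.x[e.a]);
    double dy = m.wrapdy(m.y[e.b] - m.y[e.a]);
    double l = std::sqrt(dx * dx + dy * dy);
    if (l < 1e-14) continue;
    // E = gamma * l; force pulls endpoints together
    fx[e.a] += gamma * dx / l; fy[e.a] += gamma * dy / l;
    fx[e.b] -= gamma * dx / l; fy[e.b] -= gamma * dy / l;
  }
}

// Fast local RNG for the Brownian noise (xoshiro256++), seeded from the R
// random stream once per chunk so runs remain reproducible under set.seed.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

}  // namespace

// [[Rcpp::export]]
List vm_cell_geometry(NumericVector vx, NumericVector vy, List loops,
                      double Lx, double Ly) {
  Mesh m = build_mesh(vx, vy, loops, Lx, Ly);
  NumericVector area(m.nc), perim(m.nc), cx(m.nc), cy(m.nc);
  std::vector<double> ux, uy;
  for (int c = 0; c < m.nc; ++c) {
    int n = unwrap_loop(m, c, ux, uy);
    double A, P;
    cell_area_perim(ux, uy, n, A, P);
    area[c] = A; perim[c] = P;
    // polygon centroid on the unwrapped copy, wrapped back into the box
    double sx = 0.0, sy = 0.0;
    for (int j = 0; j < n; ++j) {
      int k = (j + 1) % n;
      double w = ux[j] * uy[k] - ux[k] * uy[j];
      sx += (ux[j] + ux[k]) * w;
      sy += (uy[j] + uy[k]) * w;
    }
    double gx = sx / (6.0 * A), gy = sy / (6.0 * A);
    gx -= Lx * std::floor(gx / Lx);
    gy -= Ly * std::floor(gy / Ly);
    cx[c] = gx; cy[c] = gy;
  }
  return List::create(_["area"] = area, _["perim"] = perim,
                      _["cx"] = cx, _["cy"] = cy);
}

// [[Rcpp::export]]
double vm_energy(NumericVector vx, NumericVector vy, List loops,
                 IntegerVector ctype, NumericVector A0, NumericVector P0,
                 double Lx, double Ly, double KA, double KP, double gamma) {
  Mesh m = build_mesh(vx, vy, loops, Lx, Ly);
  double E = 0.0;
  std::vector<double> ux, uy;
  for (int c = 0; c < m.nc; ++c) {
    int n = unwrap_loop(m, c, ux, uy);
    double A, P;
    cell_area_perim(ux, uy, n, A, P);
    if (A <= 0) stop("cell %d has non-positive area (topology error)", c + 1);
    E += KA * (A - A0[c]) * (A - A0[c]) + KP * (P - P0[c]) * (P - P0[c]);
  }
  if (gamma != 0.0) {
    std::vector<Edge> edges = build_edges(m, ctype);
    for (const auto& e : edges) {
      if (!e.het) continue;
      double dx = m.wrapdx(m.x[e.b] - m.x[e.a]);
      double dy = m.wrapdy(m.y[e.b] - m.y[e.a]);
      E += gamma * std::sqrt(dx * dx + dy * dy);
    }
  }
  return E;
}

// [[Rcpp::export]]
NumericMatrix vm_forces(NumericVector vx, NumericVector vy, List loops,
                        IntegerVector ctype, NumericVector A0,
                        NumericVector P0, double Lx, double Ly, double KA,
                        double KP, double gamma) {
  Mesh m = build_mesh(vx, vy, loops, Lx, Ly);
  std::vector<double> fx(m.nv, 0.0), fy(m.nv, 0.0);
  std::vector<double> ux, uy, sex, sey, sil;
  add_cell_forces(m, A0.begin(), P0.begin(), KA, KP, fx, fy, ux, uy, sex,
                  sey, sil);
  std::vector<Edge> edges = build_edges(m, ctype);
  add_line_tension_forces(m, edges, gamma, fx, fy);
  NumericMatrix F(m.nv, 2);
  for (int v = 0; v < m.nv; ++v) { F(v, 0) = fx[v]; F(v, 1) = fy[v]; }
  return F;
}

// Per-edge table with junctional tensions dE/dl (Eq. of state: twice the
// perimeter-spring coefficient of each adjacent cell, plus the boundary line
// tension on heterotypic edges). Positive = tensile, negative = compressed.
// [[Rcpp::export]]
DataFrame vm_edge_table(NumericVector vx, NumericVector vy, List loops,
                        IntegerVector ctype, NumericVector A0,
                        NumericVector P0, double Lx, double Ly, double KA,
                        double KP, double gamma) {
  Mesh m = build_mesh(vx, vy, loops, Lx, Ly);
  std::vector<Edge> edges = build_edges(m, ctype);
  int ne = edges.size();
  // cell perimeters
  std::vector<double> perim(m.nc);
  std::vector<double> ux, uy;
  for (int c = 0; c < m.nc; ++c) {
    int n = unwrap_loop(m, c, ux, uy);
    double A, P;
    cell_area_perim(ux, uy, n, A, P);
    perim[c] = P;
  }
  IntegerVector a(ne), b(ne), c1(ne), c2(ne);
  NumericVector len(ne), tension(ne);
  LogicalVector het(ne);
  for (int i = 0; i < ne; ++i) {
    const Edge& e = edges[i];
    a[i] = e.a + 1; b[i] = e.b + 1;
    c1[i] = e.c1 + 1; c2[i] = e.c2 >= 0 ? e.c2 + 1 : NA_INTEGER;
    double dx = m.wrapdx(m.x[e.b] - m.x[e.a]);
    double dy = m.wrapdy(m.y[e.b] - m.y[e.a]);
    len[i] = std::sqrt(dx * dx + dy * dy);
    double t = 2.0 * KP * (perim[e.c1] - P0[e.c1]);
    if (e.c2 >= 0) t += 2.0 * KP * (perim[e.c2] - P0[e.c2]);
    if (e.het) t += gamma;
    tension[i] = t;
    het[i] = e.het;
  }
  return DataFrame::create(_["a"] = a, _["b"] = b, _["c1"] = c1, _["c2"] = c2,
                           _["length"] = len, _["het"] = het,
                           _["tension"] = tension);
}

// Advance the tissue by up to nsteps forward-Euler steps of the overdamped
// Brownian dynamics  r <- r + mu F dt + eta,  eta ~ N(0, 2 mu T dt) per
// component. gamma may vary per step. Every check_every steps edges are
// scanned for lengths below l_t1; on detection the chunk stops and reports
// the offending edge so the caller can perform the topological move.
// skip_a/skip_b (1-based vertex pairs) lists edges to ignore in that check.
// [[Rcpp::export]]
List vm_run_chunk(NumericVector vx, NumericVector vy, List loops,
                  IntegerVector ctype, NumericVector A0, NumericVector P0,
                  double Lx, double Ly, double KA, double KP, double mu,
                  double temperature, double dt, NumericVector gamma,
                  double l_t1, int check_every, IntegerVector skip_a,
                  IntegerVector skip_b, double f_tol = 0.0) {
  Mesh m = build_mesh(vx, vy, loops, Lx, Ly);
  std::vector<Edge> edges = build_edges(m, ctype);
  std::vector<char> skip(edges.size(), 0);
  if (skip_a.size() > 0) {
    std::unordered_map<long long, int> idx;
    for (size_t i = 0; i < edges.size(); ++i)
      idx[(long long)edges[i].a * m.nv + edges[i].b] = (int)i;
    for (int i = 0; i < skip_a.size(); ++i) {
      int a = std::min(skip_a[i], skip_b[i]) - 1;
      int b = std::max(skip_a[i], skip_b[i]) - 1;
      auto it = idx.find((long long)a * m.nv + b);
      if (it != idx.end()) skip[it->second] = 1;
    }
  }
  int nsteps = gamma.size();
  double noise_sd = std::sqrt(2.0 * mu * temperature * dt);
  std::vector<double> fx(m.nv), fy(m.nv);
  std::vector<double> ux, uy, sex, sey, sil;  // per-cell scratch
  const double* A0p = A0.begin();
  const double* P0p = P0.begin();
  uint64_t seed = (uint64_t)(::unif_rand() * 4294967296.0) << 32;
  seed ^= (uint64_t)(::unif_rand() * 4294967296.0);
  Xoshiro rng(seed);
  int t1_a = -1, t1_b = -1, steps_done = 0;
  for (int s = 0; s < nsteps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    add_cell_forces(m, A0p, P0p, KA, KP, fx, fy, ux, uy, sex, sey, sil);
    add_line_tension_forces(m, edges, gamma[s], fx, fy);
    if (temperature > 0.0) {
      // Box-Muller pairs from the chunk's local stream
      for (int v = 0; v < m.nv; ++v) {
        double u1 = rng.unif();
        while (u1 <= 0.0) u1 = rng.unif();
        double u2 = rng.unif();
        double r = noise_sd * std::sqrt(-2.0 * std::log(u1));
        double X = m.x[v] + mu * fx[v] * dt + r * std::cos(2.0 * M_PI * u2);
        double Y = m.y[v] + mu * fy[v] * dt + r * std::sin(2.0 * M_PI * u2);
        if (X >= Lx) X -= Lx; else if (X < 0) X += Lx;
        if (Y >= Ly) Y -= Ly; else if (Y < 0) Y += Ly;
        m.x[v] = X; m.y[v] = Y;
      }
    } else {
      for (int v = 0; v < m.nv; ++v) {
        double X = m.x[v] + mu * fx[v] * dt;
        double Y = m.y[v] + mu * fy[v] * dt;
        if (X >= Lx) X -= Lx; else if (X < 0) X += Lx;
        if (Y >= Ly) Y -= Ly; else if (Y < 0) Y += Ly;
        m.x[v] = X; m.y[v] = Y;
      }
    }
    ++steps_done;
    bool at_check = steps_done % check_every == 0 || s == nsteps - 1;
    if (f_tol > 0.0 && temperature == 0.0 && at_check) {
      // converged zero-temperature relaxation: stop early
      double fmax2 = 0.0;
      for (int v = 0; v < m.nv; ++v) {
        double f2 = fx[v] * fx[v] + fy[v] * fy[v];
        if (f2 > fmax2) fmax2 = f2;
      }
      if (fmax2 < f_tol * f_tol) break;
    }
    if (l_t1 > 0.0 && at_check) {
      for (size_t i = 0; i < edges.size(); ++i) {
        if (skip[i]) continue;
        const Edge& e = edges[i];
        double dx = m.wrapdx(m.x[e.b] - m.x[e.a]);
        double dy = m.wrapdy(m.y[e.b] - m.y[e.a]);
        if (dx * dx + dy * dy < l_t1 * l_t1) { t1_a = e.a; t1_b = e.b; break; }
      }
      if (t1_a >= 0) break;
    }
  }
  return List::create(_["vx"] = NumericVector(m.x.begin(), m.x.end()),
                      _["vy"] = NumericVector(m.y.begin(), m.y.end()),
                      _["steps_done"] = steps_done,
                      _["t1_a"] = t1_a + 1, _["t1_b"] = t1_b + 1);
}
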
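// Core of the dynamically triangulated Monte-Carlo membrane simulator:
// mesh connectivity, discrete differential geometry (cotangent mean
// curvature, barycentric vertex areas), energy terms, active forces with
// alignment/inhibition, constraint checks with a uniform spatial grid,
// and the Metropolis sweep engine.  All lengths are in lmin units and all
// energies in kBT.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline void sub3(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}

// ---------------------------------------------------------------------------
// Mesh connectivity
// ---------------------------------------------------------------------------

struct Mesh {
  int nv = 0, nt = 0, ne = 0;
  std::vector<double> X;            // 3*nv positions
  std::vector<int> T;               // 3*nt vertex ids (0-based)
  std::vector<int> e0, e1;          // edge endpoints
  std::vector<int> et0, et1;        // incident triangles per edge (et1 = -1 on boundary)
  std::vector<std::vector<int>> vnbr, vedge, vtri;
  std::vector<char> vboundary;      // 1 if vertex touches a boundary edge
  bool closed = true;

  void build(const NumericMatrix& pos, const IntegerMatrix& tri) {
    nv = pos.nrow();
    nt = tri.nrow();
    X.resize(3 * nv);
    for (int i = 0; i < nv; ++i) {
      X[3 * i] = pos(i, 0); X[3 * i + 1] = pos(i, 1); X[3 * i + 2] = pos(i, 2);
    }
    T.resize(3 * nt);
    for (int t = 0; t < nt; ++t)
      for (int c = 0; c < 3; ++c) {
        int v = tri(t, c) - 1;
        if (v < 0 || v >= nv) stop("triangle %d references vertex out of range", t + 1);
        T[3 * t + c] = v;
      }
    vnbr.assign(nv, {}); vedge.assign(nv, {}); vtri.assign(nv, {});
    e0.clear(); e1.clear(); et0.clear(); et1.clear();
    std::unordered_map<long long, int> emap;
    emap.reserve(3 * nt);
    for (int t = 0; t < nt; ++t) {
      for (int c = 0; c < 3; ++c) {
        int a = T[3 * t + c], b = T[3 * t + (c + 1) % 3];
        vtri[a].push_back(t);
        long long key = (long long)std::min(a, b) * (long long)nv + std::max(a, b);
        auto it = emap.find(key);
        if (it == emap.end()) {
          int e = (int)e0.size();
          emap[key] = e;
          e0.push_back(a); e1.push_back(b); et0.push_back(t); et1.push_back(-1);
          vnbr[a].push_back(b); vedge[a].push_back(e);
          vnbr[b].push_back(a); vedge[b].push_back(e);
        } else {
          int e = it->second;
          if (et1[e] != -1) stop("edge %d-%d has more than 2 incident triangles", a + 1, b + 1);
          et1[e] = t;
        }
      }
    }
    ne = (int)e0.size();
    closed = true;
    vboundary.assign(nv, 0);
    for (int e = 0; e < ne; ++e) {
      if (et1[e] == -1) {
        closed = false;
        vboundary[e0[e]] = 1; vboundary[e1[e]] = 1;
      }
    }
  }

  int findEdge(int a, int b) const {
    const std::vector<int>& nb = vnbr[a];
    for (size_t q = 0; q < nb.size(); ++q) if (nb[q] == b) return vedge[a][q];
    return -1;
  }
  int degree(int v) const { return (int)vnbr[v].size(); }
};

// ---------------------------------------------------------------------------
// Per-vertex discrete geometry
// ---------------------------------------------------------------------------

struct VGeom {
  double A;      // barycentric vertex area
  double h;      // signed mean curvature (C1+C2)/2
  double n[3];   // outward unit normal
};

// Cotangent mean-curvature vector with barycentric areas; sign of h from the
// dot product with the area-weighted outward normal.
static VGeom vertexGeom(const Mesh& m, int v, bool err_degenerate = true) {
  VGeom g; g.A = 0.0; g.h = 0.0; g.n[0] = g.n[1] = g.n[2] = 0.0;
  double Hv[3] = {0, 0, 0}, nn[3] = {0, 0, 0};
  const double* xv = &m.X[3 * v];
  for (int t : m.vtri[v]) {
    int a = m.T[3 * t], b = m.T[3 * t + 1], c = m.T[3 * t + 2];
    if (b == v) { int tmp = a; a = b; b = c; c = tmp; }
    else if (c == v) { int tmp = c; c = b; b = a; a = tmp; }
    // now a == v, orientation preserved
    const double* xb = &m.X[3 * b];
    const double* xc = &m.X[3 * c];
    double ab[3], ac[3], cr[3];
    sub3(xb, xv, ab); sub3(xc, xv, ac);
    cross3(ab, ac, cr);                       // 2 * area * outward face normal
    double two_area = norm3(cr);
    if (two_area <= 1e-12) {
      if (err_degenerate) stop("degenerate (zero-area) triangle %d", t + 1);
      continue;
    }
    g.A += 0.5 * two_area / 3.0;
    nn[0] += cr[0]; nn[1] += cr[1]; nn[2] += cr[2];
    // cot at b (opposite edge v-c) and cot at c (opposite edge v-b)
    double bv[3], bc[3], cv[3], cb[3], crb[3], crc[3];
    sub3(xv, xb, bv); sub3(xc, xb, bc);
    sub3(xv, xc, cv); sub3(xb, xc, cb);
    cross3(bv, bc, crb); cross3(cv, cb, crc);
    double cotb = dot3(bv, bc) / norm3(crb);
    double cotc = dot3(cv, cb) / norm3(crc);
    Hv[0] += cotc * (xv[0] - xb[0]) + cotb * (xv[0] - xc[0]);
    Hv[1] += cotc * (xv[1] - xb[1]) + cotb * (xv[1] - xc[1]);
    Hv[2] += cotc * (xv[2] - xb[2]) + cotb * (xv[2] - xc[2]);
  }
  double nl = norm3(nn);
  if (nl > 0) { g.n[0] = nn[0] / nl; g.n[1] = nn[1] / nl; g.n[2] = nn[2] / nl; }
  if (g.A > 0) {
    double hm = norm3(Hv) / (4.0 * g.A);
    g.h = (dot3(Hv, g.n) >= 0) ? hm : -hm;
  }
  return g;
}

// ---------------------------------------------------------------------------
// Model parameters (species 0 = bare membrane)
// ---------------------------------------------------------------------------

struct Params {
  int K = 0;                              // number of CMC species
  std::vector<double> c0, f;              // indexed 0..K (0 = bare)
  std::vector<char> inhib, aligned;
  std::vector<double> w;                  // (K+1)^2 binding matrix, row/col 0 = 0
  double kappa = 20.0, w_ad = 0.0, z0 = 0.0;
  bool wall = false;
  double s_align = 0.0, r_align = 0.0;
  int inhib_mode = 0;                     // 0 none, 1 proportional, 2 disabling
  double beta = 1.0;
  double lmin = 1.0, lmax = 1.7, step = 0.15;

  double wv(int la, int lb) const { return w[la * (K + 1) + lb]; }
};

static Params makeParams(const NumericVector& c0, const NumericVector& f,
                         const LogicalVector& inhib, const LogicalVector& aligned,
                         const NumericMatrix& wmat, double kappa, double w_ad,
                         double z0, bool wall, double s_align, double r_align,
                         int inhib_mode, double beta, double lmin, double lmax,
                         double step) {
  Params P;
  P.K = c0.size();
  P.c0.assign(P.K + 1, 0.0); P.f.assign(P.K + 1, 0.0);
  P.inhib.assign(P.K + 1, 0); P.aligned.assign(P.K + 1, 0);
  for (int k = 0; k < P.K; ++k) {
    P.c0[k + 1] = c0[k]; P.f[k + 1] = f[k];
    P.inhib[k + 1] = inhib[k] ? 1 : 0; P.aligned[k + 1] = aligned[k] ? 1 : 0;
  }
  P.w.assign((P.K + 1) * (P.K + 1), 0.0);
  for (int a = 0; a < P.K; ++a)
    for (int b = 0; b < P.K; ++b)
      P.w[(a + 1) * (P.K + 1) + (b + 1)] = wmat(a, b);
  P.kappa = kappa; P.w_ad = w_ad; P.z0 = z0; P.wall = wall;
  P.s_align = s_align; P.r_align = r_align; P.inhib_mode = inhib_mode;
  P.beta = beta; P.lmin = lmin; P.lmax = lmax; P.step = step;
  return P;
}

// Bending energy share of one vertex: kappa/2 (2 h - C0)^2 A.
// Boundary vertices of open meshes carry no defined curvature and are skipped.
static double bendOne(const Mesh& m, int v, const std::vector<int>& lab, const Params& P) {
  if (!m.closed && m.vboundary[v]) return 0.0;
  VGeom g = vertexGeom(m, v);
  double d = 2.0 * g.h - P.c0[lab[v]];
  return 0.5 * P.kappa * d * d * g.A;
}

static double adhOne(const Mesh& m, int v, const Params& P) {
  if (!P.wall || P.w_ad == 0.0) return 0.0;
  double z = m.X[3 * v + 2];
  return (std::fabs(z - P.z0) <= P.lmin) ? -P.w_ad : 0.0;
}

static void totalEnergies(const Mesh& m, const std::vector<int>& lab, const Params& P,
                          double& ebend, double& ebind, double& eadh) {
  ebend = ebind = eadh = 0.0;
  for (int v = 0; v < m.nv; ++v) {
    ebend += bendOne(m, v, lab, P);
    eadh += adhOne(m, v, P);
  }
  for (int e = 0; e < m.ne; ++e) ebind -= P.wv(lab[m.e0[e]], lab[m.e1[e]]);
}

static double totalArea(const Mesh& m) {
  double A = 0.0;
  for (int t = 0; t < m.nt; ++t) {
    const double* xa = &m.X[3 * m.T[3 * t]];
    const double* xb = &m.X[3 * m.T[3 * t + 1]];
    const double* xc = &m.X[3 * m.T[3 * t + 2]];
    double ab[3], ac[3], cr[3];
    sub3(xb, xa, ab); sub3(xc, xa, ac); cross3(ab, ac, cr);
    A += 0.5 * norm3(cr);
  }
  return A;
}

static double signedVolume(const Mesh& m) {
  double V = 0.0;
  for (int t = 0; t < m.nt; ++t) {
    const double* xa = &m.X[3 * m.T[3 * t]];
    const double* xb = &m.X[3 * m.T[3 * t + 1]];
    const double* xc = &m.X[3 * m.T[3 * t + 2]];
    double cr[3];
    cross3(xb, xc, cr);
    V += dot3(xa, cr) / 6.0;
  }
  return V;
}

// ---------------------------------------------------------------------------
// Uniform spatial grid for the hard-core self-avoidance check
// ---------------------------------------------------------------------------

struct Grid {
  double cell = 1.0;
  std::unordered_map<long long, std::vector<int>> cells;

  static long long mix(long long ix, long long iy, long long iz) {
    return ix * 73856093LL ^ iy * 19349663LL ^ iz * 83492791LL;
  }
  long long keyOf(const double* p) const {
    return mix((long long)std::floor(p[0] / cell),
               (long long)std::floor(p[1] / cell),
               (long long)std::floor(p[2] / cell));
  }
  void insert(int v, const double* p) { cells[keyOf(p)].push_back(v); }
  void remove(int v, const double* p) {
    auto it = cells.find(keyOf(p));
    if (it == cells.end()) return;
    std::vector<int>& c = it->second;
    for (size_t q = 0; q < c.size(); ++q)
      if (c[q] == v) { c[q] = c.back(); c.pop_back(); break; }
  }
  void move(int v, const double* oldp, const double* newp) {
    if (keyOf(oldp) == keyOf(newp)) return;
    remove(v, oldp); insert(v, newp);
  }
  // any vertex (other than v and the marked graph neighbours) strictly
  // closer than dmin to p?
  bool tooClose(const Mesh& m, int v, const double* p, double dmin,
                const std::vector<char>& nbrmark) const {
    double d2min = dmin * dmin;
    long long ix = (long long)std::floor(p[0] / cell);
    long long iy = (long long)std::floor(p[1] / cell);
    long long iz = (long long)std::floor(p[2] / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(mix(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int u : it->second) {
            if (u == v || nbrmark[u]) continue;
            const double* xu = &m.X[3 * u];
            double d0 = p[0] - xu[0], d1 = p[1] - xu[1], d2 = p[2] - xu[2];
            if (d0 * d0 + d1 * d1 + d2 * d2 < d2min) return true;
          }
        }
    return false;
  }
};

// ---------------------------------------------------------------------------
// Engine
// ---------------------------------------------------------------------------

struct Engine {
  Mesh m;
  Params P;
  std::vector<int> lab;
  Grid grid;
  std::vector<char> nbrmark;
  std::vector<double> vnormal;   // 3*nv, refreshed every sweep when alignment on
  std::vector<double> adir;      // 3*nv aligned force directions
  bool any_aligned = false;
  long long acc_move = 0, try_move = 0, acc_flip = 0, try_flip = 0;
  // caches kept exactly in sync with the configuration
  std::vector<double> ebend_c;   // per-vertex bending energy share
  double ebind_c = 0.0;          // total binding energy
  bool cache_on = false;

  void init(const NumericMatrix& pos, const IntegerMatrix& tri,
            const IntegerVector& labels, const Params& pars) {
    m.build(pos, tri);
    if (!m.closed) stop("simulation requires a closed mesh");
    P = pars;
    lab.assign(m.nv, 0);
    for (int i = 0; i < m.nv; ++i) lab[i] = labels[i];
    grid.cell = P.lmin;
    for (int v = 0; v < m.nv; ++v) grid.insert(v, &m.X[3 * v]);
    nbrmark.assign(m.nv, 0);
    for (int k = 1; k <= P.K; ++k)
      if (P.aligned[k] && P.s_align > 0) any_aligned = true;
    adir.assign(3 * m.nv, 0.0);
    if (any_aligned) refreshAlignment();
    ebend_c.resize(m.nv);
    for (int v = 0; v < m.nv; ++v) ebend_c[v] = bendOne(m, v, lab, P);
    ebind_c = 0.0;
    for (int e = 0; e < m.ne; ++e) ebind_c -= P.wv(lab[m.e0[e]], lab[m.e1[e]]);
    cache_on = true;
  }

  void computeNormals() {
    vnormal.assign(3 * m.nv, 0.0);
    for (int t = 0; t < m.nt; ++t) {
      int a = m.T[3 * t], b = m.T[3 * t + 1], c = m.T[3 * t + 2];
      double ab[3], ac[3], cr[3];
      sub3(&m.X[3 * b], &m.X[3 * a], ab);
      sub3(&m.X[3 * c], &m.X[3 * a], ac);
      cross3(ab, ac, cr);
      for (int q = 0; q < 3; ++q) {
        vnormal[3 * a + q] += cr[q];
        vnormal[3 * b + q] += cr[q];
        vnormal[3 * c + q] += cr[q];
      }
    }
    for (int v = 0; v < m.nv; ++v) {
      double nl = norm3(&vnormal[3 * v]);
      if (nl > 0) for (int q = 0; q < 3; ++q) vnormal[3 * v + q] /= nl;
    }
  }

  // connected components of CMC-occupied vertices (any species)
  void clusterIds(std::vector<int>& clid, std::vector<std::vector<int>>& members) const {
    clid.assign(m.nv, 0);
    members.clear();
    std::vector<int> stack;
    int next = 0;
    for (int s = 0; s < m.nv; ++s) {
      if (lab[s] == 0 || clid[s] != 0) continue;
      ++next;
      members.push_back({});
      clid[s] = next;
      stack.push_back(s);
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        members[next - 1].push_back(v);
        for (int u : m.vnbr[v])
          if (lab[u] != 0 && clid[u] == 0) { clid[u] = next; stack.push_back(u); }
      }
    }
  }

  // Vicsek-like aligned directions: normalize(n_i + s * sum of normals of
  // cluster-mates within Euclidean distance r).
  void refreshAlignment() {
    computeNormals();
    std::vector<int> clid;
    std::vector<std::vector<int>> members;
    clusterIds(clid, members);
    double r2 = P.r_align * P.r_align;
    for (int v = 0; v < m.nv; ++v) {
      if (lab[v] == 0) continue;
      if (!(P.aligned[lab[v]] && P.s_align > 0)) {
        for (int q = 0; q < 3; ++q) adir[3 * v + q] = vnormal[3 * v + q];
        continue;
      }
      double d[3] = { vnormal[3 * v], vnormal[3 * v + 1], vnormal[3 * v + 2] };
      const double* xv = &m.X[3 * v];
      for (int u : members[clid[v] - 1]) {
        if (u == v) continue;
        double dv[3];
        sub3(&m.X[3 * u], xv, dv);
        if (dot3(dv, dv) > r2) continue;
        for (int q = 0; q < 3; ++q) d[q] += P.s_align * vnormal[3 * u + q];
      }
      double nl = norm3(d);
      if (nl < 1e-12) {  // antiparallel cancellation: fall back to the normal
        for (int q = 0; q < 3; ++q) adir[3 * v + q] = vnormal[3 * v + q];
      } else {
        for (int q = 0; q < 3; ++q) adir[3 * v + q] = d[q] / nl;
      }
    }
  }

  double forceMag(int v) const {
    int l = lab[v];
    double f = P.f[l];
    if (f == 0.0 || P.inhib_mode == 0) return f;
    const std::vector<int>& nb = m.vnbr[v];
    if (P.inhib_mode == 1) {
      double s = 0.0;
      for (int u : nb) s += P.inhib[lab[u]] ? 0.0 : 1.0;
      return f * s / (double)nb.size();
    }
    for (int u : nb) if (P.inhib[lab[u]]) return 0.0;
    return f;
  }

  bool metropolis(double expo) {
    double u = unif_rand();
    return (expo >= 0.0) || (u < std::exp(expo));
  }

  void attemptMove(int v) {
    ++try_move;
    double oldp[3] = { m.X[3 * v], m.X[3 * v + 1], m.X[3 * v + 2] };
    double p[3];
    for (int q = 0; q < 3; ++q) p[q] = oldp[q] + P.step * (2.0 * unif_rand() - 1.0);
    // hard constraints: edge bounds, wall, self-avoidance
    const std::vector<int>& nb = m.vnbr[v];
    double l2min = P.lmin * P.lmin, l2max = P.lmax * P.lmax;
    for (int u : nb) {
      double d[3];
      sub3(p, &m.X[3 * u], d);
      double d2 = dot3(d, d);
      if (d2 <= l2min || d2 >= l2max) return;
    }
    if (P.wall && p[2] < P.z0 - P.lmin) return;
    for (int u : nb) nbrmark[u] = 1;
    bool clash = grid.tooClose(m, v, p, P.lmin, nbrmark);
    for (int u : nb) nbrmark[u] = 0;
    if (clash) return;
    // local energy difference (vertex + 1-ring curvature/area, adhesion of v)
    double ebef = ebend_c[v] + adhOne(m, v, P);
    for (int u : nb) ebef += ebend_c[u];
    // active work, with the pre-move direction
    double W = 0.0;
    double fm = (lab[v] != 0) ? forceMag(v) : 0.0;
    if (fm != 0.0) {
      double dir[3];
      if (P.aligned[lab[v]] && P.s_align > 0) {
        dir[0] = adir[3 * v]; dir[1] = adir[3 * v + 1]; dir[2] = adir[3 * v + 2];
      } else {
        VGeom g = vertexGeom(m, v);
        dir[0] = g.n[0]; dir[1] = g.n[1]; dir[2] = g.n[2];
      }
      double dx[3];
      sub3(p, oldp, dx);
      W = -fm * dot3(dir, dx);
    }
    m.X[3 * v] = p[0]; m.X[3 * v + 1] = p[1]; m.X[3 * v + 2] = p[2];
    double bv = bendOne(m, v, lab, P);
    double eaft = bv + adhOne(m, v, P);
    double bnb[64];
    int nn = (int)nb.size();
    if (nn > 64) stop("vertex degree exceeds 64");
    for (int q = 0; q < nn; ++q) {
      bnb[q] = bendOne(m, nb[q], lab, P);
      eaft += bnb[q];
    }
    double dE = eaft - ebef;
    if (metropolis(-P.beta * (dE + W))) {
      grid.move(v, oldp, p);
      ebend_c[v] = bv;
      for (int q = 0; q < nn; ++q) ebend_c[nb[q]] = bnb[q];
      ++acc_move;
    } else {
      m.X[3 * v] = oldp[0]; m.X[3 * v + 1] = oldp[1]; m.X[3 * v + 2] = oldp[2];
    }
  }

  // Replace the shared edge of two triangles by the opposite diagonal.
  // t1 must contain the directed edge i->j; afterwards t1=(i,l,k), t2=(l,j,k).
  void doFlip(int e) {
    int i = m.e0[e], j = m.e1[e], t1 = m.et0[e], t2 = m.et1[e];
    bool fwd = false;
    for (int c = 0; c < 3; ++c)
      if (m.T[3 * t1 + c] == i && m.T[3 * t1 + (c + 1) % 3] == j) { fwd = true; break; }
    if (!fwd) std::swap(i, j);
    int k = -1, l = -1;
    for (int c = 0; c < 3; ++c) {
      int v = m.T[3 * t1 + c];
      if (v != i && v != j) k = v;
      v = m.T[3 * t2 + c];
      if (v != i && v != j) l = v;
    }
    m.T[3 * t1] = i; m.T[3 * t1 + 1] = l; m.T[3 * t1 + 2] = k;
    m.T[3 * t2] = l; m.T[3 * t2 + 1] = j; m.T[3 * t2 + 2] = k;
    // vertex->triangle incidence
    auto eraseVal = [](std::vector<int>& v, int x) {
      for (size_t q = 0; q < v.size(); ++q)
        if (v[q] == x) { v[q] = v.back(); v.pop_back(); return; }
    };
    eraseVal(m.vtri[j], t1); m.vtri[l].push_back(t1);
    eraseVal(m.vtri[i], t2); m.vtri[k].push_back(t2);
    // adjacency: drop i-j, add k-l (reusing edge id e)
    auto dropAdj = [&](int a, int b) {
      std::vector<int>& nb = m.vnbr[a];
      std::vector<int>& ed = m.vedge[a];
      for (size_t q = 0; q < nb.size(); ++q)
        if (nb[q] == b) { nb[q] = nb.back(); nb.pop_back(); ed[q] = ed.back(); ed.pop_back(); return; }
    };
    dropAdj(i, j); dropAdj(j, i);
    m.vnbr[k].push_back(l); m.vedge[k].push_back(e);
    m.vnbr[l].push_back(k); m.vedge[l].push_back(e);
    m.e0[e] = k; m.e1[e] = l;
    // the quad boundary edges j-k and i-l swap their incident-triangle slot
    auto replaceTri = [&](int ee, int from, int to) {
      if (m.et0[ee] == from) m.et0[ee] = to; else m.et1[ee] = to;
    };
    replaceTri(m.findEdge(j, k), t1, t2);
    replaceTri(m.findEdge(i, l), t2, t1);
  }

  // 0 ok; 1 boundary; 2 duplicate edge; 3 degree; 4 length
  int flipFeasible(int e) const {
    if (m.et1[e] < 0) return 1;
    int i = m.e0[e], j = m.e1[e], t1 = m.et0[e], t2 = m.et1[e];
    int k = -1, l = -1;
    for (int c = 0; c < 3; ++c) {
      int v = m.T[3 * t1 + c];
      if (v != i && v != j) k = v;
      v = m.T[3 * t2 + c];
      if (v != i && v != j) l = v;
    }
    if (m.findEdge(k, l) >= 0) return 2;
    if (m.degree(i) <= 3 || m.degree(j) <= 3) return 3;
    double d[3];
    sub3(&m.X[3 * k], &m.X[3 * l], d);
    double dd = norm3(d);
    if (dd <= P.lmin || dd >= P.lmax) return 4;
    return 0;
  }

  void attemptFlip(int e) {
    ++try_flip;
    if (flipFeasible(e) != 0) return;
    int i = m.e0[e], j = m.e1[e], t1 = m.et0[e], t2 = m.et1[e];
    int k = -1, l = -1;
    for (int c = 0; c < 3; ++c) {
      int v = m.T[3 * t1 + c];
      if (v != i && v != j) k = v;
      v = m.T[3 * t2 + c];
      if (v != i && v != j) l = v;
    }
    double wbef = P.wv(lab[i], lab[j]), waft = P.wv(lab[k], lab[l]);
    double ebef = ebend_c[i] + ebend_c[j] + ebend_c[k] + ebend_c[l] - wbef;
    doFlip(e);
    double bi = bendOne(m, i, lab, P), bj = bendOne(m, j, lab, P);
    double bk = bendOne(m, k, lab, P), bl = bendOne(m, l, lab, P);
    double eaft = bi + bj + bk + bl - waft;
    double dE = eaft - ebef;
    if (metropolis(-P.beta * dE)) {
      ebend_c[i] = bi; ebend_c[j] = bj; ebend_c[k] = bk; ebend_c[l] = bl;
      ebind_c += wbef - waft;
      ++acc_flip;
    } else {
      doFlip(e);  // exact connectivity involution
    }
  }

  void sweep() {
    if (any_aligned) refreshAlignment();
    for (int a = 0; a < m.nv; ++a) {
      int v = (int)(unif_rand() * m.nv);
      if (v >= m.nv) v = m.nv - 1;
      attemptMove(v);
    }
    for (int a = 0; a < m.ne; ++a) {
      int e = (int)(unif_rand() * m.ne);
      if (e >= m.ne) e = m.ne - 1;
      attemptFlip(e);
    }
  }
};

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_geometry(NumericMatrix pos, IntegerMatrix tri) {
  Mesh m;
  m.build(pos, tri);
  NumericVector A(m.nv), h(m.nv);
  NumericMatrix N(m.nv, 3);
  for (int v = 0; v < m.nv; ++v) {
    VGeom g = vertexGeom(m, v);
    A[v] = g.A;
    h[v] = (!m.closed && m.vboundary[v]) ? NA_REAL : g.h;
    N(v, 0) = g.n[0]; N(v, 1) = g.n[1]; N(v, 2) = g.n[2];
  }
  return List::create(_["area"] = A, _["h"] = h, _["normal"] = N);
}

// [[Rcpp::export]]
List cpp_edges(IntegerMatrix tri, int nv) {
  NumericMatrix pos(nv, 3);
  Mesh m;
  m.build(pos, tri);
  IntegerMatrix E(m.ne, 2);
  IntegerVector ntri(m.ne);
  for (int e = 0; e < m.ne; ++e) {
    int a = m.e0[e], b = m.e1[e];
    E(e, 0) = std::min(a, b) + 1; E(e, 1) = std::max(a, b) + 1;
    ntri[e] = (m.et1[e] == -1) ? 1 : 2;
  }
  return List::create(_["edges"] = E, _["ntri"] = ntri, _["closed"] = m.closed);
}

// [[Rcpp::export]]
double cpp_signed_volume(NumericMatrix pos, IntegerMatrix tri) {
  Mesh m;
  m.build(pos, tri);
  return signedVolume(m);
}

// [[Rcpp::export]]
double cpp_total_area(NumericMatrix pos, IntegerMatrix tri) {
  Mesh m;
  m.build(pos, tri);
  return totalArea(m);
}

// [[Rcpp::export]]
NumericVector cpp_energy_terms(NumericMatrix pos, IntegerMatrix tri,
                               IntegerVector labels, NumericVector c0,
                               NumericVector f, LogicalVector inhib,
                               LogicalVector aligned, NumericMatrix wmat,
                               double kappa, double w_ad, double z0, bool wall,
                               double lmin) {
  Mesh m;
  m.build(pos, tri);
  Params P = makeParams(c0, f, inhib, aligned, wmat, kappa, w_ad, z0, wall,
                        0, 0, 0, 1, lmin, 1.7 * lmin, 0.15 * lmin);
  std::vector<int> lab(labels.begin(), labels.end());
  double eb, ei, ea;
  totalEnergies(m, lab, P, eb, ei, ea);
  return NumericVector::create(_["bending"] = eb, _["binding"] = ei, _["adhesion"] = ea);
}

// Local energy difference for a proposed displacement of one vertex
// (bending of the vertex and its 1-ring plus its adhesion term; binding is
// untouched by a displacement).
// [[Rcpp::export]]
double cpp_move_delta(NumericMatrix pos, IntegerMatrix tri, IntegerVector labels,
                      NumericVector c0, NumericVector f, LogicalVector inhib,
                      LogicalVector aligned, NumericMatrix wmat, double kappa,
                      double w_ad, double z0, bool wall, double lmin,
                      int vertex, NumericVector newpos) {
  Mesh m;
  m.build(pos, tri);
  Params P = makeParams(c0, f, inhib, aligned, wmat, kappa, w_ad, z0, wall,
                        0, 0, 0, 1, lmin, 1.7 * lmin, 0.15 * lmin);
  std::vector<int> lab(labels.begin(), labels.end());
  int v = vertex - 1;
  if (v < 0 || v >= m.nv) stop("vertex out of range");
  double ebef = bendOne(m, v, lab, P) + adhOne(m, v, P);
  for (int u : m.vnbr[v]) ebef += bendOne(m, u, lab, P);
  m.X[3 * v] = newpos[0]; m.X[3 * v + 1] = newpos[1]; m.X[3 * v + 2] = newpos[2];
  double eaft = bendOne(m, v, lab, P) + adhOne(m, v, P);
  for (int u : m.vnbr[v]) eaft += bendOne(m, u, lab, P);
  return eaft - ebef;
}

// Connectivity-only bond flip with validity checking.
// [[Rcpp::export]]
List cpp_flip_edge(NumericMatrix pos, IntegerMatrix tri, int va, int vb,
                   double lmin, double lmax) {
  Mesh m;
  m.build(pos, tri);
  NumericVector dummy(0);
  LogicalVector ldummy(0);
  NumericMatrix wdummy(0, 0);
  Engine eng;
  IntegerVector labels(m.nv);
  Params P = makeParams(dummy, dummy, ldummy, ldummy, wdummy, 20, 0, 0, false,
                        0, 0, 0, 1, lmin, lmax, 0.15);
  eng.m = m; eng.P = P;
  int e = eng.m.findEdge(va - 1, vb - 1);
  if (e < 0) stop("edge %d-%d is not in the mesh", va, vb);
  int code = eng.flipFeasible(e);
  const char* reasons[] = {"ok", "boundary", "duplicate-edge", "degree", "length"};
  if (code != 0)
    return List::create(_["ok"] = false, _["reason"] = reasons[code],
                        _["triangles"] = tri);
  eng.doFlip(e);
  IntegerMatrix out(eng.m.nt, 3);
  for (int t = 0; t < eng.m.nt; ++t)
    for (int c = 0; c < 3; ++c) out(t, c) = eng.m.T[3 * t + c] + 1;
  return List::create(_["ok"] = true, _["reason"] = "ok", _["triangles"] = out,
                      _["new_edge"] = IntegerVector::create(eng.m.e0[e] + 1, eng.m.e1[e] + 1));
}

// Energy difference (bending + binding) of a bond flip, without mutating.
// [[Rcpp::export]]
List cpp_flip_delta(NumericMatrix pos, IntegerMatrix tri, IntegerVector labels,
                    NumericVector c0, NumericVector f, LogicalVector inhib,
                    LogicalVector aligned, NumericMatrix wmat, double kappa,
                    double w_ad, double z0, bool wall, double lmin, double lmax,
                    int va, int vb) {
  Engine eng;
  eng.m.build(pos, tri);
  eng.P = makeParams(c0, f, inhib, aligned, wmat, kappa, w_ad, z0, wall,
                     0, 0, 0, 1, lmin, lmax, 0.15);
  std::vector<int> lab(labels.begin(), labels.end());
  eng.lab = lab;
  int e = eng.m.findEdge(va - 1, vb - 1);
  if (e < 0) stop("edge %d-%d is not in the mesh", va, vb);
  int code = eng.flipFeasible(e);
  const char* reasons[] = {"ok", "boundary", "duplicate-edge", "degree", "length"};
  if (code != 0)
    return List::create(_["ok"] = false, _["reason"] = reasons[code], _["delta"] = NA_REAL);
  int i = eng.m.e0[e], j = eng.m.e1[e], t1 = eng.m.et0[e], t2 = eng.m.et1[e];
  int k = -1, l = -1;
  for (int c = 0; c < 3; ++c) {
    int v = eng.m.T[3 * t1 + c];
    if (v != i && v != j) k = v;
    v = eng.m.T[3 * t2 + c];
    if (v != i && v != j) l = v;
  }
  double ebef = bendOne(eng.m, i, lab, eng.P) + bendOne(eng.m, j, lab, eng.P) +
                bendOne(eng.m, k, lab, eng.P) + bendOne(eng.m, l, lab, eng.P) -
                eng.P.wv(lab[i], lab[j]);
  eng.doFlip(e);
  double eaft = bendOne(eng.m, i, lab, eng.P) + bendOne(eng.m, j, lab, eng.P) +
                bendOne(eng.m, k, lab, eng.P) + bendOne(eng.m, l, lab, eng.P) -
                eng.P.wv(lab[k], lab[l]);
  return List::create(_["ok"] = true, _["reason"] = "ok", _["delta"] = eaft - ebef);
}

// Constraint predicate for a proposed vertex displacement.
// Returns "ok", "edge-length", "wall" or "self-avoidance".
// [[Rcpp::export]]
String cpp_check_constraints(NumericMatrix pos, IntegerMatrix tri, int vertex,
                             NumericVector newpos, double lmin, double lmax,
                             bool wall, double z0) {
  Mesh m;
  m.build(pos, tri);
  int v = vertex - 1;
  if (v < 0 || v >= m.nv) stop("vertex out of range");
  double p[3] = { newpos[0], newpos[1], newpos[2] };
  double l2min = lmin * lmin, l2max = lmax * lmax;
  for (int u : m.vnbr[v]) {
    double d[3];
    sub3(p, &m.X[3 * u], d);
    double d2 = dot3(d, d);
    if (d2 <= l2min || d2 >= l2max) return "edge-length";
  }
  if (wall && p[2] < z0 - lmin) return "wall";
  std::vector<char> nbrmark(m.nv, 0);
  for (int u : m.vnbr[v]) nbrmark[u] = 1;
  for (int u = 0; u < m.nv; ++u) {
    if (u == v || nbrmark[u]) continue;
    double d[3];
    sub3(p, &m.X[3 * u], d);
    if (dot3(d, d) < l2min) return "self-avoidance";
  }
  return "ok";
}

// Cluster id per vertex (0 for bare membrane), ids in discovery order.
// [[Rcpp::export]]
IntegerVector cpp_clusters(IntegerMatrix tri, IntegerVector labels, int nv) {
  NumericMatrix pos(nv, 3);
  Engine eng;
  eng.m.build(pos, tri);
  eng.lab.assign(labels.begin(), labels.end());
  std::vector<int> clid;
  std::vector<std::vector<int>> members;
  eng.clusterIds(clid, members);
  return IntegerVector(clid.begin(), clid.end());
}

// Active force directions for every vertex (zero rows for bare vertices).
// [[Rcpp::export]]
NumericMatrix cpp_force_directions(NumericMatrix pos, IntegerMatrix tri,
                                   IntegerVector labels, NumericVector c0,
                                   NumericVector f, LogicalVector inhib,
                                   LogicalVector aligned, double s_align,
                                   double r_align) {
  Engine eng;
  NumericMatrix wmat(c0.size(), c0.size());
  Params P = makeParams(c0, f, inhib, aligned, wmat, 20, 0, 0, false,
                        s_align, r_align, 0, 1, 1, 1.7, 0.15);
  eng.m.build(pos, tri);
  eng.P = P;
  eng.lab.assign(labels.begin(), labels.end());
  eng.adir.assign(3 * eng.m.nv, 0.0);
  eng.refreshAlignment();
  NumericMatrix D(eng.m.nv, 3);
  for (int v = 0; v < eng.m.nv; ++v) {
    if (eng.lab[v] == 0) continue;
    for (int q = 0; q < 3; ++q) D(v, q) = eng.adir[3 * v + q];
  }
  return D;
}

// Per-vertex force magnitudes after inhibition.
// [[Rcpp::export]]
NumericVector cpp_force_magnitudes(IntegerMatrix tri, IntegerVector labels,
                                   NumericVector c0, NumericVector f,
                                   LogicalVector inhib, LogicalVector aligned,
                                   int inhib_mode, int nv) {
  NumericMatrix pos(nv, 3);
  NumericMatrix wmat(c0.size(), c0.size());
  Engine eng;
  eng.m.build(pos, tri);
  eng.P = makeParams(c0, f, inhib, aligned, wmat, 20, 0, 0, false,
                     0, 0, inhib_mode, 1, 1, 1.7, 0.15);
  eng.lab.assign(labels.begin(), labels.end());
  NumericVector out(nv);
  for (int v = 0; v < nv; ++v) out[v] = (eng.lab[v] == 0) ? 0.0 : eng.forceMag(v);
  return out;
}

// Run n Metropolis sweeps (V vertex-move attempts + E bond-flip attempts
// each).  Uses R's RNG; seed with set.seed() before calling.
// [[Rcpp::export]]
List cpp_run_sweeps(NumericMatrix pos, IntegerMatrix tri, IntegerVector labels,
                    NumericVector c0, NumericVector f, LogicalVector inhib,
                    LogicalVector aligned, NumericMatrix wmat, double kappa,
                    double w_ad, double z0, bool wall, double s_align,
                    double r_align, int inhib_mode, double beta, double lmin,
                    double lmax, double step, int nsweeps) {
  Engine eng;
  Params P = makeParams(c0, f, inhib, aligned, wmat, kappa, w_ad, z0, wall,
                        s_align, r_align, inhib_mode, beta, lmin, lmax, step);
  eng.init(pos, tri, labels, P);
  NumericMatrix stats(nsweeps, 7);
  colnames(stats) = CharacterVector::create("sweep", "e_bend", "e_bind", "e_adh",
                                            "area", "acc_move", "acc_flip");
  for (int sidx = 0; sidx < nsweeps; ++sidx) {
    long long am0 = eng.acc_move, tm0 = eng.try_move;
    long long af0 = eng.acc_flip, tf0 = eng.try_flip;
    eng.sweep();
    double eb = 0.0, ea = 0.0;
    for (int v = 0; v < eng.m.nv; ++v) {
      eb += eng.ebend_c[v];
      ea += adhOne(eng.m, v, eng.P);
    }
    stats(sidx, 0) = sidx + 1;
    stats(sidx, 1) = eb; stats(sidx, 2) = eng.ebind_c; stats(sidx, 3) = ea;
    stats(sidx, 4) = totalArea(eng.m);
    stats(sidx, 5) = (eng.try_move > tm0)
      ? (double)(eng.acc_move - am0) / (double)(eng.try_move - tm0) : NA_REAL;
    stats(sidx, 6) = (eng.try_flip > tf0)
      ? (double)(eng.acc_flip - af0) / (double)(eng.try_flip - tf0) : NA_REAL;
    if (sidx % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix outpos(eng.m.nv, 3);
  for (int v = 0; v < eng.m.nv; ++v)
    for (int q = 0; q < 3; ++q) outpos(v, q) = eng.m.X[3 * v + q];
  IntegerMatrix outtri(eng.m.nt, 3);
  for (int t = 0; t < eng.m.nt; ++t)
    for (int c = 0; c < 3; ++c) outtri(t, c) = eng.m.T[3 * t + c] + 1;
  return List::create(_["positions"] = outpos, _["triangles"] = outtri,
                      _["stats"] = stats);
}
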
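#ifndef CURVACTIN_MECHANICS_H
#define CURVACTIN_MECHANICS_H

// Semiflexible filament mechanics: harmonic segment stretching, cosine
// bending at hinges, pairwise 1/r^4 excluded volume between cylinder
// segments (fixed-order Gauss-Legendre quadrature with a short-range cap),
// exponential boundary repulsion from the slab faces, and branch-bond
// potentials (stretch, two angular terms, dihedral). Analytic gradients for
// every term; Polak-Ribiere conjugate-gradient minimization with a
// backtracking (Armijo) line search. A per-bead mobility mask supports
// minimizing a local neighbourhood with the remainder frozen: frozen-frozen
// interaction terms are constant and skipped, so reduced-energy decrease
// implies total-energy decrease.

#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <limits>
#include <unordered_map>

namespace curvmech {

constexpr double L_SEG_MARGIN = 30.0;  // nm, covers one segment half-length

struct MechParams {
  double k_str = 100.0;     // pN/nm
  double k_bend = 2588.0;   // pN nm  (L_p k_B T / l_cyl)
  double kvol = 1680.0;     // excluded-volume constant
  double eps_b = 100.0;     // pN nm, boundary repulsion at contact
  double lambda = 2.7;      // nm, boundary screening length
  double Lx = 8000, Ly = 8000, Lz = 500;  // slab box, nm
  double ev_cut = 100.0;    // nm, neighbour-list cutoff for excluded volume
  double rmin = 1.0;        // nm, singularity cap
  double k_bstr = 100.0;    // pN/nm, branch bond stretch (no 1/2 factor)
  double k_bb1 = 100.0;     // pN nm, parent-bond angle (ref pi/2)
  double k_bb2 = 480.0;     // pN nm, parent-offspring angle (ref 1.222 rad)
  double k_bdih = 50.0;     // pN nm, dihedral (k cos phi)
  double theta_branch = 1.222;  // rad, 70 deg
  double L0_bond = 6.0;     // nm, branch bond resting length
  int nquad = 8;            // Gauss-Legendre order per segment
};

struct EnergyTerms {
  double stretch = 0, bend = 0, excl = 0, boundary = 0;
  double b_str = 0, b_bend1 = 0, b_bend2 = 0, b_dih = 0;
  double total() const {
    return stretch + bend + excl + boundary + b_str + b_bend1 + b_bend2 + b_dih;
  }
};

struct Bond {
  int a, b;      // parent segment bead indices (minus->plus order)
  double s;      // site fraction along the parent segment, in [0,1]
  int c, d;      // offspring minus-end bead and the next bead
  double L0;     // bond resting length
};

struct MechSystem {
  int n = 0;                        // beads
  std::vector<double> x;            // 3n coordinates (nm)
  std::vector<int> seg_a, seg_b;    // segment bead indices
  std::vector<int> seg_fil;         // filament id per segment
  std::vector<int> seg_idx;         // index of segment within its filament
  std::vector<double> seg_rest;     // resting length per segment
  std::vector<Bond> bonds;
  std::vector<char> mobile;         // per bead; empty => all mobile
  bool reduced = false;             // skip all-frozen terms

  bool is_mobile(int i) const { return mobile.empty() || mobile[i]; }
};

inline const double* gl_nodes(int n) {
  static const double n2[] = {0.21132486540518713, 0.7886751345948129};
  static const double n4[] = {0.06943184420297371, 0.33000947820757187,
                              0.6699905217924281, 0.9305681557970262};
  static const double n8[] = {0.019855071751231856, 0.10166676129318664,
                              0.2372337950418355, 0.40828267875217505,
                              0.5917173212478249, 0.7627662049581645,
                              0.8983332387068134, 0.9801449282487682};
  if (n == 2) return n2;
  if (n == 4) return n4;
  return n8;
}
inline const double* gl_weights(int n) {
  static const double w2[] = {0.5, 0.5};
  static const double w4[] = {0.17392742256872693, 0.32607257743127305,
                              0.32607257743127305, 0.17392742256872693};
  static const double w8[] = {0.05061426814518813, 0.11119051722668723,
                              0.15685332293894372, 0.18134189168918097,
                              0.18134189168918097, 0.15685332293894372,
                              0.11119051722668723, 0.05061426814518813};
  if (n == 2) return w2;
  if (n == 4) return w4;
  return w8;
}

inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// ---- stretching -----------------------------------------------------------

inline double stretch_energy_pair(const double* p, const double* q,
                                  double rest, double k) {
  double d[3]; vsub(q, p, d);
  double l = vnorm(d);
  double e = l - rest;
  return 0.5 * k * e * e;
}

inline void stretch_grad_pair(const double* p, const double* q, double rest,
                              double k, double* gp, double* gq) {
  double d[3]; vsub(q, p, d);
  double l = vnorm(d);
  if (l < 1e-12) return;
  double f = k * (l - rest) / l;
  for (int m = 0; m < 3; ++m) { gq[m] += f * d[m]; gp[m] -= f * d[m]; }
}

// ---- bending (cosine hinge) ----------------------------------------------
// U = k (1 - cos theta), theta between u = b - a and v = c - b.

inline double bend_energy_triplet(const double* a, const double* b,
                                  const double* c, double k) {
  double u[3], v[3];
  vsub(b, a, u); vsub(c, b, v);
  double nu = vnorm(u), nv = vnorm(v);
  if (nu < 1e-12 || nv < 1e-12) return 0.0;
  double ct = vdot(u, v) / (nu * nv);
  ct = std::max(-1.0, std::min(1.0, ct));
  return k * (1.0 - ct);
}

inline void bend_grad_triplet(const double* a, const double* b,
                              const double* c, double k,
                              double* ga, double* gb, double* gc) {
  double u[3], v[3];
  vsub(b, a, u); vsub(c, b, v);
  double nu = vnorm(u), nv = vnorm(v);
  if (nu < 1e-12 || nv < 1e-12) return;
  double inv = 1.0 / (nu * nv);
  double ct = vdot(u, v) * inv;
  // d(cos)/du and d(cos)/dv
  double dcu[3], dcv[3];
  for (int m = 0; m < 3; ++m) {
    dcu[m] = v[m] * inv - ct * u[m] / (nu * nu);
    dcv[m] = u[m] * inv - ct * v[m] / (nv * nv);
  }
  // U = k (1 - cos) => dU/dcos = -k; u = b - a, v = c - b
  for (int m = 0; m < 3; ++m) {
    double gu = -k * dcu[m], gv = -k * dcv[m];
    ga[m] -= gu;
    gb[m] += gu - gv;
    gc[m] += gv;
  }
}

// ---- excluded volume ------------------------------------------------------
// U = kvol int_0^1 int_0^1 ds dt / |r_i(s) - r_j(t)|^4, fixed-order GL
// quadrature; pair distances capped below rmin (capped contributions carry
// zero gradient).

inline double ev_pair_energy(const double* i0, const double* i1,
                             const double* j0, const double* j1,
                             double kvol, int nq, double rmin) {
  const double* xs = gl_nodes(nq);
  const double* ws = gl_weights(nq);
  double rmin2 = rmin * rmin, acc = 0;
  for (int a = 0; a < nq; ++a) {
    double s = xs[a];
    double pa[3] = {(1 - s) * i0[0] + s * i1[0], (1 - s) * i0[1] + s * i1[1],
                    (1 - s) * i0[2] + s * i1[2]};
    for (int b = 0; b < nq; ++b) {
      double t = xs[b];
      double pb[3] = {(1 - t) * j0[0] + t * j1[0], (1 - t) * j0[1] + t * j1[1],
                      (1 - t) * j0[2] + t * j1[2]};
      double d0 = pa[0] - pb[0], d1 = pa[1] - pb[1], d2 = pa[2] - pb[2];
      double r2 = d0 * d0 + d1 * d1 + d2 * d2;
      if (r2 < rmin2) r2 = rmin2;
      acc += ws[a] * ws[b] / (r2 * r2);
    }
  }
  return kvol * acc;
}

inline void ev_pair_grad(const double* i0, const double* i1, const double* j0,
                         const double* j1, double kvol, int nq, double rmin,
                         double* gi0, double* gi1, double* gj0, double* gj1) {
  const double* xs = gl_nodes(nq);
  const double* ws = gl_weights(nq);
  double rmin2 = rmin * rmin;
  for (int a = 0; a < nq; ++a) {
    double s = xs[a];
    double pa[3] = {(1 - s) * i0[0] + s * i1[0], (1 - s) * i0[1] + s * i1[1],
                    (1 - s) * i0[2] + s * i1[2]};
    for (int b = 0; b < nq; ++b) {
      double t = xs[b];
      double pb[3] = {(1 - t) * j0[0] + t * j1[0], (1 - t) * j0[1] + t * j1[1],
                      (1 - t) * j0[2] + t * j1[2]};
      double d[3] = {pa[0] - pb[0], pa[1] - pb[1], pa[2] - pb[2]};
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 <= rmin2) continue;  // capped: flat
      double r4 = r2 * r2;
      double coef = -4.0 * kvol * ws[a] * ws[b] / (r4 * r2);
      for (int m = 0; m < 3; ++m) {
        double g = coef * d[m];
        gi0[m] += (1 - s) * g; gi1[m] += s * g;
        gj0[m] -= (1 - t) * g; gj1[m] -= t * g;
      }
    }
  }
}

// ---- boundary -------------------------------------------------------------
// Six slab faces; U = eps exp(-d / lambda) per face with signed distance
// (beads pushed back when outside).

inline double boundary_energy_bead(const double* p, const MechParams& par) {
  double L[3] = {par.Lx, par.Ly, par.Lz};
  double acc = 0;
  for (int m = 0; m < 3; ++m) {
    acc += std::exp(-p[m] / par.lambda);
    acc += std::exp(-(L[m] - p[m]) / par.lambda);
  }
  return par.eps_b * acc;
}

inline void boundary_grad_bead(const double* p, const MechParams& par,
                               double* g) {
  double L[3] = {par.Lx, par.Ly, par.Lz};
  double c = par.eps_b / par.lambda;
  for (int m = 0; m < 3; ++m) {
    g[m] += -c * std::exp(-p[m] / par.lambda);
    g[m] += c * std::exp(-(L[m] - p[m]) / par.lambda);
  }
}

// Inward boundary force (pN, vector) on a bead: F = -grad U_boundary.
inline void boundary_force_bead(const double* p, const MechParams& par,
                                double* f) {
  double g[3] = {0, 0, 0};
  boundary_grad_bead(p, par, g);
  f[0] = -g[0]; f[1] = -g[1]; f[2] = -g[2];
}

// Distance from a bead to the nearest slab face (signed; negative outside).
inline double boundary_distance(const double* p, const MechParams& par) {
  double L[3] = {par.Lx, par.Ly, par.Lz};
  double d = std::numeric_limits<double>::infinity();
  for (int m = 0; m < 3; ++m) {
    d = std::min(d, p[m]);
    d = std::min(d, L[m] - p[m]);
  }
  return d;
}

// ---- branch bond ----------------------------------------------------------
// Site point P = (1-s) A + s B on the parent segment; u = B - A (parent
// tangent), bvec = C - P (bond), v = D - C (offspring direction).
// U_str  = k_bstr (|bvec| - L0)^2                (printed without 1/2)
// U_b1   = k_bb1 (1 - cos(theta_ub - pi/2))
// U_b2   = k_bb2 (1 - cos(theta_uv - theta_branch))
// U_dih  = k_bdih cos(n1, n2), n1 = u x bvec, n2 = bvec x v

struct BranchGeom {
  double u[3], bvec[3], v[3];
  double P[3];
  double Lb;
  bool ok;
};

inline BranchGeom branch_geometry(const MechSystem& sys, const Bond& bd) {
  BranchGeom g;
  const double* A = &sys.x[3 * bd.a];
  const double* B = &sys.x[3 * bd.b];
  const double* C = &sys.x[3 * bd.c];
  const double* D = &sys.x[3 * bd.d];
  for (int m = 0; m < 3; ++m) {
    g.P[m] = (1 - bd.s) * A[m] + bd.s * B[m];
    g.u[m] = B[m] - A[m];
    g.v[m] = D[m] - C[m];
  }
  vsub(C, g.P, g.bvec);
  g.Lb = vnorm(g.bvec);
  g.ok = (vnorm(g.u) > 1e-12 && vnorm(g.v) > 1e-12 && g.Lb > 1e-12);
  return g;
}

inline double angle_offset_energy(const double* u, const double* v,
                                  double offset, double k) {
  double nu = vnorm(u), nv = vnorm(v);
  if (nu < 1e-12 || nv < 1e-12) return 0.0;
  double ct = vdot(u, v) / (nu * nv);
  ct = std::max(-1.0, std::min(1.0, ct));
  double theta = std::acos(ct);
  return k * (1.0 - std::cos(theta - offset));
}

// Gradient of angle_offset_energy wrt u and v (accumulated).
inline void angle_offset_grad(const double* u, const double* v, double offset,
                              double k, double* gu, double* gv) {
  double nu = vnorm(u), nv = vnorm(v);
  if (nu < 1e-12 || nv < 1e-12) return;
  double inv = 1.0 / (nu * nv);
  double ct = vdot(u, v) * inv;
  ct = std::max(-1.0, std::min(1.0, ct));
  double theta = std::acos(ct);
  double st = std::sin(theta);
  if (st < 1e-8) return;  // gradient undefined at collinear; measure zero
  // dU/d(cos theta) = k sin(theta - offset) * (-1/sin theta)
  double dUdc = -k * std::sin(theta - offset) / st;
  for (int m = 0; m < 3; ++m) {
    gu[m] += dUdc * (v[m] * inv - ct * u[m] / (nu * nu));
    gv[m] += dUdc * (u[m] * inv - ct * v[m] / (nv * nv));
  }
}

inline double dihedral_energy(const double* u, const double* b,
                              const double* v, double k, bool* skipped) {
  double n1[3], n2[3];
  vcross(u, b, n1);
  vcross(b, v, n2);
  double h1 = vnorm(n1), h2 = vnorm(n2);
  if (h1 < 1e-9 || h2 < 1e-9) {  // collinear: plane normal undefined
    if (skipped) *skipped = true;
    return 0.0;
  }
  if (skipped) *skipped = false;
  return k * vdot(n1, n2) / (h1 * h2);
}

inline void dihedral_grad(const double* u, const double* b, const double* v,
                          double k, double* gu, double* gb, double* gv) {
  double n1[3], n2[3];
  vcross(u, b, n1);
  vcross(b, v, n2);
  double h1 = vnorm(n1), h2 = vnorm(n2);
  if (h1 < 1e-9 || h2 < 1e-9) return;
  double g = vdot(n1, n2);
  double dg_u[3], dg_b[3], dg_v[3], t1[3], t2[3];
  vcross(b, n2, dg_u);                       // d(n1.n2)/du
  vcross(n2, u, t1); vcross(v, n1, t2);      // d(n1.n2)/db
  for (int m = 0; m < 3; ++m) dg_b[m] = t1[m] + t2[m];
  vcross(n1, b, dg_v);                       // d(n1.n2)/dv
  double dh1_u[3], dh1_b[3], dh2_b[3], dh2_v[3];
  vcross(b, n1, t1); for (int m = 0; m < 3; ++m) dh1_u[m] = t1[m] / h1;
  vcross(n1, u, t1); for (int m = 0; m < 3; ++m) dh1_b[m] = t1[m] / h1;
  vcross(v, n2, t1); for (int m = 0; m < 3; ++m) dh2_b[m] = t1[m] / h2;
  vcross(n2, b, t1); for (int m = 0; m < 3; ++m) dh2_v[m] = t1[m] / h2;
  double H = h1 * h2, H2 = H * H;
  for (int m = 0; m < 3; ++m) {
    gu[m] += k * (dg_u[m] * H - g * dh1_u[m] * h2) / H2;
    gb[m] += k * (dg_b[m] * H - g * (dh1_b[m] * h2 + h1 * dh2_b[m])) / H2;
    gv[m] += k * (dg_v[m] * H - g * h1 * dh2_v[m]) / H2;
  }
}

// ---- neighbour list for excluded volume -----------------------------------

struct CellList {
  double cell;                 // cell edge (>= cutoff)
  double ox, oy, oz;           // origin
  int ncx, ncy, ncz;
  std::unordered_map<int64_t, std::vector<int>> cells;

  int64_t key(int cx, int cy, int cz) const {
    return (int64_t)cx + 100000LL * ((int64_t)cy + 100000LL * (int64_t)cz);
  }
  void build(const MechSystem& sys, double cutoff) {
    cell = std::max(cutoff, 1.0);
    int ns = sys.seg_a.size();
    double inf = std::numeric_limits<double>::infinity();
    ox = oy = oz = inf;
    for (int i = 0; i < sys.n; ++i) {
      ox = std::min(ox, sys.x[3 * i]);
      oy = std::min(oy, sys.x[3 * i + 1]);
      oz = std::min(oz, sys.x[3 * i + 2]);
    }
    // In reduced mode only pairs touching a mobile bead contribute, so only
    // segments within one cutoff of the mobile bounding box can matter.
    bool use_box = sys.reduced && !sys.mobile.empty();
    double blo[3] = {inf, inf, inf}, bhi[3] = {-inf, -inf, -inf};
    if (use_box) {
      for (int i = 0; i < sys.n; ++i) {
        if (!sys.mobile[i]) continue;
        for (int m = 0; m < 3; ++m) {
          blo[m] = std::min(blo[m], sys.x[3 * i + m]);
          bhi[m] = std::max(bhi[m], sys.x[3 * i + m]);
        }
      }
      double margin = cutoff + L_SEG_MARGIN;
      for (int m = 0; m < 3; ++m) { blo[m] -= margin; bhi[m] += margin; }
    }
    cells.clear();
    for (int sgi = 0; sgi < ns; ++sgi) {
      if (use_box) {
        const double* pa = &sys.x[3 * sys.seg_a[sgi]];
        const double* pb = &sys.x[3 * sys.seg_b[sgi]];
        bool in = true;
        for (int m = 0; m < 3 && in; ++m) {
          double lo = std::min(pa[m], pb[m]), hi = std::max(pa[m], pb[m]);
          if (hi < blo[m] || lo > bhi[m]) in = false;
        }
        if (!in) continue;
      }
      double mx = 0.5 * (sys.x[3 * sys.seg_a[sgi]] + sys.x[3 * sys.seg_b[sgi]]);
      double my = 0.5 * (sys.x[3 * sys.seg_a[sgi] + 1] + sys.x[3 * sys.seg_b[sgi] + 1]);
      double mz = 0.5 * (sys.x[3 * sys.seg_a[sgi] + 2] + sys.x[3 * sys.seg_b[sgi] + 2]);
      int cx = (int)std::floor((mx - ox) / cell);
      int cy = (int)std::floor((my - oy) / cell);
      int cz = (int)std::floor((mz - oz) / cell);
      cells[key(cx, cy, cz)].push_back(sgi);
    }
  }
  template <typename F>
  void for_pairs(const MechSystem& sys, F&& f) const {
    for (auto& kv : cells) {
      int64_t k = kv.first;
      int cz = (int)(k / (100000LL * 100000LL));
      int64_t rem = k - (int64_t)cz * 100000LL * 100000LL;
      int cy = (int)(rem / 100000LL);
      int cx = (int)(rem - (int64_t)cy * 100000LL);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            auto it = cells.find(key(cx + dx, cy + dy, cz + dz));
            if (it == cells.end()) continue;
            bool same = (dx == 0 && dy == 0 && dz == 0);
            // visit each unordered pair once
            if (!same && (dx < 0 || (dx == 0 && (dy < 0 || (dy == 0 && dz < 0)))))
              continue;
            const std::vector<int>& a = kv.second;
            const std::vector<int>& b = it->second;
            for (size_t i = 0; i < a.size(); ++i) {
              size_t j0 = same ? i + 1 : 0;
              for (size_t j = j0; j < b.size(); ++j) f(a[i], b[j]);
            }
          }
    }
  }
};

inline bool ev_pair_excluded(const MechSystem& sys, int i, int j) {
  // same segment or adjacent segments on the same filament
  if (i == j) return true;
  if (sys.seg_fil[i] == sys.seg_fil[j] &&
      std::abs(sys.seg_idx[i] - sys.seg_idx[j]) <= 1)
    return true;
  return false;
}

inline bool ev_pair_within(const MechSystem& sys, int i, int j, double cut) {
  double dx = 0.5 * (sys.x[3 * sys.seg_a[i]] + sys.x[3 * sys.seg_b[i]]) -
              0.5 * (sys.x[3 * sys.seg_a[j]] + sys.x[3 * sys.seg_b[j]]);
  double dy = 0.5 * (sys.x[3 * sys.seg_a[i] + 1] + sys.x[3 * sys.seg_b[i] + 1]) -
              0.5 * (sys.x[3 * sys.seg_a[j] + 1] + sys.x[3 * sys.seg_b[j] + 1]);
  double dz = 0.5 * (sys.x[3 * sys.seg_a[i] + 2] + sys.x[3 * sys.seg_b[i] + 2]) -
              0.5 * (sys.x[3 * sys.seg_a[j] + 2] + sys.x[3 * sys.seg_b[j] + 2]);
  return dx * dx + dy * dy + dz * dz <= cut * cut;
}

// ---- full system energy / gradient ---------------------------------------

inline bool term_active2(const MechSystem& sys, int a, int b) {
  return !sys.reduced || sys.is_mobile(a) || sys.is_mobile(b);
}
inline bool term_active3(const MechSystem& sys, int a, int b, int c) {
  return !sys.reduced || sys.is_mobile(a) || sys.is_mobile(b) || sys.is_mobile(c);
}

inline EnergyTerms system_energy(const MechSystem& sys, const MechParams& par) {
  EnergyTerms E;
  int ns = sys.seg_a.size();
  for (int i = 0; i < ns; ++i) {
    if (!term_active2(sys, sys.seg_a[i], sys.seg_b[i])) continue;
    E.stretch += stretch_energy_pair(&sys.x[3 * sys.seg_a[i]],
                                     &sys.x[3 * sys.seg_b[i]],
                                     sys.seg_rest[i], par.k_str);
  }
  for (int i = 0; i + 1 < ns; ++i) {
    if (sys.seg_fil[i] != sys.seg_fil[i + 1]) continue;
    if (sys.seg_idx[i] + 1 != sys.seg_idx[i + 1]) continue;
    int a = sys.seg_a[i], b = sys.seg_b[i], c = sys.seg_b[i + 1];
    if (!term_active3(sys, a, b, c)) continue;
    E.bend += bend_energy_triplet(&sys.x[3 * a], &sys.x[3 * b], &sys.x[3 * c],
                                  par.k_bend);
  }
  if (par.kvol > 0 && ns > 1) {
    CellList cl;
    cl.build(sys, par.ev_cut);
    double acc = 0;
    cl.for_pairs(sys, [&](int i, int j) {
      if (sys.reduced &&
          !sys.is_mobile(sys.seg_a[i]) && !sys.is_mobile(sys.seg_b[i]) &&
          !sys.is_mobile(sys.seg_a[j]) && !sys.is_mobile(sys.seg_b[j]))
        return;
      if (ev_pair_excluded(sys, i, j)) return;
      if (!ev_pair_within(sys, i, j, par.ev_cut)) return;
      acc += ev_pair_energy(&sys.x[3 * sys.seg_a[i]], &sys.x[3 * sys.seg_b[i]],
                            &sys.x[3 * sys.seg_a[j]], &sys.x[3 * sys.seg_b[j]],
                            par.kvol, par.nquad, par.rmin);
    });
    E.excl = acc;
  }
  if (par.eps_b > 0) {
    for (int i = 0; i < sys.n; ++i) {
      if (sys.reduced && !sys.is_mobile(i)) continue;
      E.boundary += boundary_energy_bead(&sys.x[3 * i], par);
    }
  }
  for (const Bond& bd : sys.bonds) {
    if (sys.reduced && !sys.is_mobile(bd.a) && !sys.is_mobile(bd.b) &&
        !sys.is_mobile(bd.c) && !sys.is_mobile(bd.d))
      continue;
    BranchGeom g = branch_geometry(sys, bd);
    if (!g.ok) continue;
    double e = g.Lb - bd.L0;
    E.b_str += par.k_bstr * e * e;
    E.b_bend1 += angle_offset_energy(g.u, g.bvec, M_PI / 2, par.k_bb1);
    E.b_bend2 += angle_offset_energy(g.u, g.v, par.theta_branch, par.k_bb2);
    E.b_dih += dihedral_energy(g.u, g.bvec, g.v, par.k_bdih, nullptr);
  }
  return E;
}

inline void system_grad(const MechSystem& sys, const MechParams& par,
                        std::vector<double>& grad) {
  grad.assign(3 * sys.n, 0.0);
  int ns = sys.seg_a.size();
  for (int i = 0; i < ns; ++i) {
    if (!term_active2(sys, sys.seg_a[i], sys.seg_b[i])) continue;
    stretch_grad_pair(&sys.x[3 * sys.seg_a[i]], &sys.x[3 * sys.seg_b[i]],
                      sys.seg_rest[i], par.k_str,
                      &grad[3 * sys.seg_a[i]], &grad[3 * sys.seg_b[i]]);
  }
  for (int i = 0; i + 1 < ns; ++i) {
    if (sys.seg_fil[i] != sys.seg_fil[i + 1]) continue;
    if (sys.seg_idx[i] + 1 != sys.seg_idx[i + 1]) continue;
    int a = sys.seg_a[i], b = sys.seg_b[i], c = sys.seg_b[i + 1];
    if (!term_active3(sys, a, b, c)) continue;
    bend_grad_triplet(&sys.x[3 * a], &sys.x[3 * b], &sys.x[3 * c], par.k_bend,
                      &grad[3 * a], &grad[3 * b], &grad[3 * c]);
  }
  if (par.kvol > 0 && ns > 1) {
    CellList cl;
    cl.build(sys, par.ev_cut);
    cl.for_pairs(sys, [&](int i, int j) {
      if (sys.reduced &&
          !sys.is_mobile(sys.seg_a[i]) && !sys.is_mobile(sys.seg_b[i]) &&
          !sys.is_mobile(sys.seg_a[j]) && !sys.is_mobile(sys.seg_b[j]))
        return;
      if (ev_pair_excluded(sys, i, j)) return;
      if (!ev_pair_within(sys, i, j, par.ev_cut)) return;
      ev_pair_grad(&sys.x[3 * sys.seg_a[i]], &sys.x[3 * sys.seg_b[i]],
                   &sys.x[3 * sys.seg_a[j]], &sys.x[3 * sys.seg_b[j]],
                   par.kvol, par.nquad, par.rmin,
                   &grad[3 * sys.seg_a[i]], &grad[3 * sys.seg_b[i]],
                   &grad[3 * sys.seg_a[j]], &grad[3 * sys.seg_b[j]]);
    });
  }
  if (par.eps_b > 0) {
    for (int i = 0; i < sys.n; ++i) {
      if (sys.reduced && !sys.is_mobile(i)) continue;
      boundary_grad_bead(&sys.x[3 * i], par, &grad[3 * i]);
    }
  }
  for (const Bond& bd : sys.bonds) {
    if (sys.reduced && !sys.is_mobile(bd.a) && !sys.is_mobile(bd.b) &&
        !sys.is_mobile(bd.c) && !sys.is_mobile(bd.d))
      continue;
    BranchGeom g = branch_geometry(sys, bd);
    if (!g.ok) continue;
    double gu[3] = {0, 0, 0}, gb[3] = {0, 0, 0}, gv[3] = {0, 0, 0};
    // stretch: U = k (Lb - L0)^2
    double f = 2.0 * par.k_bstr * (g.Lb - bd.L0) / g.Lb;
    for (int m = 0; m < 3; ++m) gb[m] += f * g.bvec[m];
    angle_offset_grad(g.u, g.bvec, M_PI / 2, par.k_bb1, gu, gb);
    angle_offset_grad(g.u, g.v, par.theta_branch, par.k_bb2, gu, gv);
    dihedral_grad(g.u, g.bvec, g.v, par.k_bdih, gu, gb, gv);
    // map to bead coordinates: u = B - A; bvec = C - (1-s)A - sB; v = D - C
    for (int m = 0; m < 3; ++m) {
      grad[3 * bd.a + m] += -gu[m] - (1 - bd.s) * gb[m];
      grad[3 * bd.b + m] += gu[m] - bd.s * gb[m];
      grad[3 * bd.c + m] += gb[m] - gv[m];
      grad[3 * bd.d + m] += gv[m];
    }
  }
  if (!sys.mobile.empty()) {
    for (int i = 0; i < sys.n; ++i) {
      if (!sys.mobile[i]) {
        grad[3 * i] = grad[3 * i + 1] = grad[3 * i + 2] = 0.0;
      }
    }
  }
}

inline double max_bead_force(const std::vector<double>& grad) {
  double mx = 0;
  for (size_t i = 0; i + 2 < grad.size(); i += 3) {
    double f = std::sqrt(grad[i] * grad[i] + grad[i + 1] * grad[i + 1] +
                         grad[i + 2] * grad[i + 2]);
    if (f > mx) mx = f;
  }
  return mx;
}

struct MinimizeResult {
  int iters = 0;
  double max_force = 0;
  bool converged = false;
  bool failed = false;  // NaN energy or line-search collapse before tol
  std::vector<double> energy_trace;
};

// Polak-Ribiere conjugate gradient with backtracking Armijo line search.
inline MinimizeResult cg_minimize(MechSystem& sys, const MechParams& par,
                                  double tol, int max_iter,
                                  bool keep_trace = false) {
  MinimizeResult res;
  std::vector<double> g, g_new, d;
  system_grad(sys, par, g);
  double E = system_energy(sys, par).total();
  if (!std::isfinite(E)) { res.failed = true; return res; }
  if (keep_trace) res.energy_trace.push_back(E);
  res.max_force = max_bead_force(g);
  if (res.max_force < tol) { res.converged = true; return res; }
  d.resize(g.size());
  for (size_t i = 0; i < g.size(); ++i) d[i] = -g[i];
  std::vector<double> x0;
  for (int it = 0; it < max_iter; ++it) {
    double gd = 0, dmax = 0;
    for (size_t i = 0; i < g.size(); ++i) {
      gd += g[i] * d[i];
      dmax = std::max(dmax, std::abs(d[i]));
    }
    if (gd >= 0) {  // not a descent direction: restart with steepest descent
      for (size_t i = 0; i < g.size(); ++i) d[i] = -g[i];
      gd = 0;
      for (size_t i = 0; i < g.size(); ++i) gd += g[i] * d[i];
      dmax = 0;
      for (size_t i = 0; i < g.size(); ++i) dmax = std::max(dmax, std::abs(d[i]));
    }
    if (dmax < 1e-14) break;
    double alpha = std::min(1.0, 3.0 / dmax);  // cap initial move at ~3 nm
    x0 = sys.x;
    double E_new = std::numeric_limits<double>::infinity();
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (size_t i = 0; i < sys.x.size(); ++i) sys.x[i] = x0[i] + alpha * d[i];
      E_new = system_energy(sys, par).total();
      if (std::isfinite(E_new) && E_new <= E + 1e-4 * alpha * gd) {
        ok = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!ok) {
      sys.x = x0;  // no acceptable step; treat as stalled
      break;
    }
    E = E_new;
    if (keep_trace) res.energy_trace.push_back(E);
    system_grad(sys, par, g_new);
    res.max_force = max_bead_force(g_new);
    res.iters = it + 1;
    if (!std::isfinite(res.max_force)) { res.failed = true; return res; }
    if (res.max_force < tol) { res.converged = true; g = g_new; break; }
    double num = 0, den = 0;
    for (size_t i = 0; i < g.size(); ++i) {
      num += g_new[i] * (g_new[i] - g[i]);
      den += g[i] * g[i];
    }
    double beta = den > 0 ? std::max(0.0, num / den) : 0.0;
    for (size_t i = 0; i < g.size(); ++i) d[i] = beta * d[i] - g_new[i];
    g = g_new;
  }
  if (!res.converged) {
    system_grad(sys, par, g);
    res.max_force = max_bead_force(g);
    res.converged = res.max_force < tol;
  }
  return res;
}

}  // namespace curvmech

#endif
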
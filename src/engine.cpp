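// Coupled mechanochemical simulation of dendritic actin nucleation driven by
// an immobile N-WASP copy-number map: compartmental next-reaction-method
// chemistry (activation, branching, polymerization, depolymerization,
// diffusion hopping) alternating with conjugate-gradient mechanical
// relaxation of the explicit filament network every chemistry interval
// (default 5 ms), with Brownian-ratchet rescaling of polymerization at
// boundary-loaded tips recomputed after each relaxation.
//
// Reaction scheme (per compartment; reconstruction, all rates configurable):
//   R1  NWASP + Arp_inactive -> NWASP + Arp_active   (activator retained,
//       product immobile in the compartment of activation)
//   R2  Arp_active + binding site (+ 1 G-actin) -> offspring filament at 70deg
//   R3  plus end + G-actin -> +2.7 nm                 (Brownian ratchet scaled)
//   R4  plus end -> -2.7 nm + G-actin
//   R5  Arp_active + G-actin -> de novo filament      (Arp2/3 retained at the
//       minus end, so such filaments cannot fully depolymerize)
//   R0  G-actin + G-actin -> spontaneous seed         (config-gated, off)
//   hops: G-actin and Arp_inactive between 4-neighbour compartments.

#include <Rcpp.h>
#include <random>
#include "ipq.h"
#include "mechanics.h"

using namespace Rcpp;
using namespace curvmech;

namespace {

constexpr double L_CYL = 27.0;
constexpr double L_MON = 2.7;

struct EFil {
  bool alive = false;
  bool offspring = false;  // minus end tethered or Arp-capped: not removable
  bool denovo = false;
  std::vector<double> x;  // 3 * nb
  int nb = 0;
  int tip_monomers = 0;
  std::vector<char> site_used;
  std::vector<int> site_comp;
  int tip_comp = -1;
  double ratchet = 1.0;
  double max_bond_arc = -1.0;
  int mob_lo = -1, mob_hi = -1;  // dirty bead range for reduced relaxation

  double contour() const { return L_CYL * (nb - 2) + L_MON * tip_monomers; }
  int monomers() const { return 10 * (nb - 2) + tip_monomers; }
  void mark(int lo, int hi) {
    lo = std::max(lo, 0); hi = std::min(hi, nb);
    if (mob_lo < 0) { mob_lo = lo; mob_hi = hi; }
    else { mob_lo = std::min(mob_lo, lo); mob_hi = std::max(mob_hi, hi); }
  }
};

struct BondRec {
  int parent, child;
  double arc;  // along parent from the minus end (stable: plus-end dynamics only)
};

struct Engine {
  // geometry / chemistry config
  int nx, ny, n_comp;
  double h;          // compartment edge (nm)
  double zlo = 0, zhi;
  double c_act, c_br, c_poly, k_dep, c_nuc, c_spont;
  double hopG_rate, hopA_rate;
  double t_end, dt_mech, snap_dt, full_relax_dt;
  double ratchet_F0, ratchet_range;
  int max_fils, cg_max_iter;
  double cg_tol;
  MechParams mpar;

  std::vector<long long> G, ArpI, ArpA, NW;
  std::vector<int> nbr;    // 4 * n_comp (-1 = wall)
  std::vector<int> n_nbr;  // outgoing hop directions per compartment
  std::vector<EFil> fils;
  int n_fils_alloc = 0;
  std::vector<BondRec> bonds;
  std::vector<long long> S;                 // unconsumed sites per compartment
  std::vector<std::vector<int>> tip_fils;   // per compartment

  IndexedPriorityQueue ipq;
  std::vector<double> a_cache;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  double t = 0;
  int C;  // = n_comp

  // counters
  double n_events = 0;
  long long n_act = 0, n_branch = 0, n_poly = 0, n_depoly = 0, n_hops = 0,
            n_removed = 0, n_denovo = 0, n_spont = 0;
  long long minimize_calls = 0, minimize_iters = 0;
  std::vector<int> dirty_list;

  int chan_act(int c) const { return c; }
  int chan_br(int c) const { return C + c; }
  // hop channels are aggregated over the outgoing directions of a
  // compartment (the direction is drawn uniformly at firing, which leaves
  // the method exact and quarters the channel count)
  int chan_hopG(int c) const { return 2 * C + c; }
  int chan_hopA(int c) const { return 3 * C + c; }
  int chan_nuc(int c) const { return 4 * C + c; }
  int chan_spont(int c) const { return 5 * C + c; }
  int chan_poly(int f) const { return 6 * C + 2 * f; }
  int chan_depoly(int f) const { return 6 * C + 2 * f + 1; }
  int n_chan() const { return 6 * C + 2 * max_fils; }

  int comp_of(const double* p) const {
    int cx = (int)std::floor(p[0] / h);
    int cy = (int)std::floor(p[1] / h);
    cx = std::max(0, std::min(nx - 1, cx));
    cy = std::max(0, std::min(ny - 1, cy));
    return cx + nx * cy;
  }

  double prop(int id) const {
    if (id < C) return c_act * NW[id] * ArpI[id];
    if (id < 2 * C) {
      int c = id - C;
      return (G[c] > 0) ? c_br * ArpA[c] * S[c] : 0.0;
    }
    if (id < 3 * C) {
      int c = id - 2 * C;
      return hopG_rate * G[c] * n_nbr[c];
    }
    if (id < 4 * C) {
      int c = id - 3 * C;
      return hopA_rate * ArpI[c] * n_nbr[c];
    }
    if (id < 5 * C) {
      int c = id - 4 * C;
      return c_nuc * ArpA[c] * G[c];
    }
    if (id < 6 * C) {
      int c = id - 5 * C;
      return c_spont > 0 ? c_spont * 0.5 * G[c] * (G[c] - 1) : 0.0;
    }
    int k = id - 6 * C, f = k / 2;
    const EFil& fl = fils[f];
    if (!fl.alive) return 0.0;
    if (k % 2 == 0) return c_poly * G[fl.tip_comp] * fl.ratchet;
    // depolymerization admissibility
    double ctr = fl.contour();
    if (fl.nb == 2 && fl.tip_monomers == 1) {
      return fl.offspring ? 0.0 : k_dep;  // removal event; offspring anchored
    }
    if (fl.max_bond_arc >= 0 && ctr - L_MON < fl.max_bond_arc + L_CYL / 2)
      return 0.0;  // would strand a bonded site
    return k_dep;
  }

  double draw_tau(double a) {
    if (a <= 0) return std::numeric_limits<double>::infinity();
    double r = unif(rng);
    while (r <= 0.0 || r >= 1.0) r = unif(rng);
    return t + std::log(1.0 / r) / a;
  }

  void refresh(int id) {
    double a_new = prop(id);
    double a_old = a_cache[id];
    if (a_new == a_old) return;
    double tau_old = ipq.key(id), tau_new;
    if (a_new <= 0) tau_new = std::numeric_limits<double>::infinity();
    else if (a_old <= 0 || !std::isfinite(tau_old)) tau_new = draw_tau(a_new);
    else tau_new = t + (a_old / a_new) * (tau_old - t);
    a_cache[id] = a_new;
    ipq.update(id, tau_new);
  }
  void redraw(int id) {  // for the fired channel
    a_cache[id] = prop(id);
    ipq.update(id, draw_tau(a_cache[id]));
  }

  void mark_dirty(int f) {
    if (fils[f].mob_lo < 0) dirty_list.push_back(f);
  }

  // ---- site bookkeeping ----
  void site_positions_update(int f) {
    EFil& fl = fils[f];
    int n_sites = (int)std::floor(fl.contour() / L_CYL);
    // shrink
    while ((int)fl.site_used.size() > n_sites) {
      int s = fl.site_used.size() - 1;
      if (!fl.site_used[s] && fl.site_comp[s] >= 0) {
        S[fl.site_comp[s]] -= 1;
        refresh(chan_br(fl.site_comp[s]));
      }
      fl.site_used.pop_back();
      fl.site_comp.pop_back();
    }
    // grow + recompute compartments
    int nseg = fl.nb - 1;
    for (int s = 0; s < n_sites; ++s) {
      double arc = (s + 0.5) * L_CYL;
      int k = std::min((int)std::floor(arc / L_CYL), nseg - 1);
      double frac = std::max(0.0, std::min(1.0, (arc - L_CYL * k) / L_CYL));
      double p[3];
      for (int m = 0; m < 3; ++m)
        p[m] = (1 - frac) * fl.x[3 * k + m] + frac * fl.x[3 * (k + 1) + m];
      int c_new = comp_of(p);
      if (s < (int)fl.site_comp.size()) {
        int c_old = fl.site_comp[s];
        if (c_old != c_new) {
          if (!fl.site_used[s]) {
            if (c_old >= 0) { S[c_old] -= 1; refresh(chan_br(c_old)); }
            S[c_new] += 1; refresh(chan_br(c_new));
          }
          fl.site_comp[s] = c_new;
        }
      } else {
        fl.site_used.push_back(0);
        fl.site_comp.push_back(c_new);
        S[c_new] += 1;
        refresh(chan_br(c_new));
      }
    }
  }

  void drop_all_sites(int f) {
    EFil& fl = fils[f];
    for (size_t s = 0; s < fl.site_used.size(); ++s) {
      if (!fl.site_used[s] && fl.site_comp[s] >= 0) {
        S[fl.site_comp[s]] -= 1;
        refresh(chan_br(fl.site_comp[s]));
      }
    }
    fl.site_used.clear();
    fl.site_comp.clear();
  }

  void tip_update(int f) {
    EFil& fl = fils[f];
    int c_new = fl.alive ? comp_of(&fl.x[3 * (fl.nb - 1)]) : -1;
    if (c_new == fl.tip_comp) { refresh(chan_poly(f)); return; }
    if (fl.tip_comp >= 0) {
      auto& v = tip_fils[fl.tip_comp];
      for (size_t i = 0; i < v.size(); ++i)
        if (v[i] == f) { v[i] = v.back(); v.pop_back(); break; }
    }
    fl.tip_comp = c_new;
    if (c_new >= 0) tip_fils[c_new].push_back(f);
    refresh(chan_poly(f));
  }

  void ratchet_update(int f) {
    EFil& fl = fils[f];
    if (!fl.alive) return;
    const double* tip = &fl.x[3 * (fl.nb - 1)];
    const double* prev = &fl.x[3 * (fl.nb - 2)];
    double d = boundary_distance(tip, mpar);
    double rc = 1.0;
    if (d < ratchet_range) {
      double fb[3];
      boundary_force_bead(tip, mpar, fb);
      double tdir[3];
      vsub(tip, prev, tdir);
      double nt = vnorm(tdir);
      if (nt > 1e-12) {
        double load = -(fb[0] * tdir[0] + fb[1] * tdir[1] + fb[2] * tdir[2]) / nt;
        if (load > 0) rc = std::exp(-load / ratchet_F0);
      }
    }
    if (rc != fl.ratchet) {
      fl.ratchet = rc;
      refresh(chan_poly(f));
    }
  }

  // ---- events ----
  void ev_hop(std::vector<long long>& pool, int c, bool is_G) {
    // draw the destination uniformly among the available directions
    int pick = (int)(unif(rng) * n_nbr[c]);
    if (pick >= n_nbr[c]) pick = n_nbr[c] - 1;
    int c2 = -1;
    for (int d = 0; d < 4; ++d) {
      if (nbr[4 * c + d] < 0) continue;
      if (pick == 0) { c2 = nbr[4 * c + d]; break; }
      --pick;
    }
    pool[c] -= 1;
    pool[c2] += 1;
    refresh(is_G ? chan_hopG(c) : chan_hopA(c));
    refresh(is_G ? chan_hopG(c2) : chan_hopA(c2));
    if (is_G) {
      refresh(chan_br(c)); refresh(chan_br(c2));
      refresh(chan_nuc(c)); refresh(chan_nuc(c2));
      if (c_spont > 0) { refresh(chan_spont(c)); refresh(chan_spont(c2)); }
      for (int f : tip_fils[c]) refresh(chan_poly(f));
      for (int f : tip_fils[c2]) refresh(chan_poly(f));
    } else {
      refresh(chan_act(c)); refresh(chan_act(c2));
    }
    n_hops += 1;
  }

  void ev_activate(int c) {
    ArpI[c] -= 1;
    ArpA[c] += 1;
    refresh(chan_hopA(c));
    refresh(chan_act(c));
    refresh(chan_br(c));
    refresh(chan_nuc(c));
    n_act += 1;
  }

  int alloc_fil() {
    if (n_fils_alloc >= max_fils) stop("filament capacity exceeded");
    return n_fils_alloc++;
  }

  void ev_branch(int c) {
    // choose a random unconsumed site located in compartment c
    long long pick = (long long)(unif(rng) * S[c]);
    if (pick >= S[c]) pick = S[c] - 1;
    int pf = -1, ps = -1;
    for (int f = 0; f < n_fils_alloc && pf < 0; ++f) {
      if (!fils[f].alive) continue;
      EFil& fl = fils[f];
      for (size_t s = 0; s < fl.site_used.size(); ++s) {
        if (!fl.site_used[s] && fl.site_comp[s] == c) {
          if (pick == 0) { pf = f; ps = s; break; }
          --pick;
        }
      }
    }
    if (pf < 0) stop("internal consistency error: site registry mismatch");
    EFil& par = fils[pf];
    par.site_used[ps] = 1;
    S[c] -= 1;
    ArpA[c] -= 1;
    G[c] -= 1;
    // geometry: offspring at 70 deg, azimuth uniform, bond length L0
    double arc = (ps + 0.5) * L_CYL;
    int nseg = par.nb - 1;
    int k = std::min((int)std::floor(arc / L_CYL), nseg - 1);
    double frac = std::max(0.0, std::min(1.0, (arc - L_CYL * k) / L_CYL));
    double P[3], u[3];
    for (int m = 0; m < 3; ++m) {
      P[m] = (1 - frac) * par.x[3 * k + m] + frac * par.x[3 * (k + 1) + m];
      u[m] = par.x[3 * (k + 1) + m] - par.x[3 * k + m];
    }
    double nu = vnorm(u);
    for (int m = 0; m < 3; ++m) u[m] /= nu;
    // orthonormal frame
    double ref[3] = {1, 0, 0};
    if (std::abs(u[0]) > 0.9) { ref[0] = 0; ref[1] = 1; }
    double e1[3], e2[3];
    vcross(u, ref, e1);
    double n1 = vnorm(e1);
    for (int m = 0; m < 3; ++m) e1[m] /= n1;
    vcross(u, e1, e2);
    double psi = 2 * M_PI * unif(rng);
    double bdir[3], v[3];
    double c70 = std::cos(mpar.theta_branch), s70 = std::sin(mpar.theta_branch);
    for (int m = 0; m < 3; ++m) {
      bdir[m] = std::cos(psi) * e1[m] + std::sin(psi) * e2[m];
      v[m] = c70 * u[m] + s70 * bdir[m];
    }
    int f = alloc_fil();
    EFil& off = fils[f];
    off.alive = true;
    off.offspring = true;
    off.nb = 2;
    off.tip_monomers = 1;
    off.x.resize(6);
    for (int m = 0; m < 3; ++m) {
      off.x[m] = P[m] + mpar.L0_bond * bdir[m];
      off.x[3 + m] = off.x[m] + L_MON * v[m];
    }
    bonds.push_back({pf, f, arc});
    par.max_bond_arc = std::max(par.max_bond_arc, arc);
    tip_update(f);
    site_positions_update(f);  // none yet (contour 2.7)
    redraw(chan_poly(f));
    redraw(chan_depoly(f));
    refresh(chan_depoly(pf));
    refresh(chan_br(c));
    refresh(chan_nuc(c));
    if (c_spont > 0) refresh(chan_spont(c));
    refresh(chan_hopG(c));
    for (int ff : tip_fils[c]) refresh(chan_poly(ff));
    mark_dirty(f);
    off.mark(0, off.nb);
    mark_dirty(pf);
    par.mark(k - 2, k + 3);
    n_branch += 1;
  }

  void ev_poly(int f) {
    EFil& fl = fils[f];
    int c = fl.tip_comp;
    G[c] -= 1;
    double* tip = &fl.x[3 * (fl.nb - 1)];
    double* prev = &fl.x[3 * (fl.nb - 2)];
    double td[3];
    vsub(tip, prev, td);
    double nt = vnorm(td);
    for (int m = 0; m < 3; ++m) td[m] /= (nt > 1e-12 ? nt : 1.0);
    if (fl.tip_monomers >= 10) {
      double nx_[3] = {tip[0] + L_MON * td[0], tip[1] + L_MON * td[1],
                       tip[2] + L_MON * td[2]};
      fl.x.insert(fl.x.end(), nx_, nx_ + 3);
      fl.nb += 1;
      fl.tip_monomers = 1;
    } else {
      for (int m = 0; m < 3; ++m) tip[m] += L_MON * td[m];
      fl.tip_monomers += 1;
    }
    site_positions_update(f);
    tip_update(f);
    redraw(chan_poly(f));
    refresh(chan_depoly(f));
    refresh(chan_br(c));
    refresh(chan_nuc(c));
    if (c_spont > 0) refresh(chan_spont(c));
    refresh(chan_hopG(c));
    for (int ff : tip_fils[c]) if (ff != f) refresh(chan_poly(ff));
    mark_dirty(f);
    fl.mark(fl.nb - 12, fl.nb);
    n_poly += 1;
  }

  void ev_depoly(int f) {
    EFil& fl = fils[f];
    int c = fl.tip_comp;
    G[c] += 1;
    if (fl.nb == 2 && fl.tip_monomers == 1) {
      // filament removal (seeds only; offspring are blocked)
      drop_all_sites(f);
      fl.alive = false;
      tip_update(f);
      redraw(chan_poly(f));
      redraw(chan_depoly(f));
      n_removed += 1;
    } else if (fl.tip_monomers <= 1) {
      fl.x.resize(3 * (fl.nb - 1));
      fl.nb -= 1;
      fl.tip_monomers = 10;
      site_positions_update(f);
      tip_update(f);
      redraw(chan_depoly(f));
      refresh(chan_poly(f));
      mark_dirty(f);
      fl.mark(fl.nb - 12, fl.nb);
    } else {
      double* tip = &fl.x[3 * (fl.nb - 1)];
      double* prev = &fl.x[3 * (fl.nb - 2)];
      double td[3];
      vsub(tip, prev, td);
      double nt = vnorm(td);
      for (int m = 0; m < 3; ++m) tip[m] -= L_MON * td[m] / (nt > 1e-12 ? nt : 1.0);
      fl.tip_monomers -= 1;
      site_positions_update(f);
      tip_update(f);
      redraw(chan_depoly(f));
      refresh(chan_poly(f));
      mark_dirty(f);
      fl.mark(fl.nb - 12, fl.nb);
    }
    refresh(chan_br(c));
    refresh(chan_nuc(c));
    if (c_spont > 0) refresh(chan_spont(c));
    refresh(chan_hopG(c));
    for (int ff : tip_fils[c]) if (ff != f) refresh(chan_poly(ff));
    n_depoly += 1;
  }

  // spawn a fresh 2-bead filament at a random position in compartment c
  int spawn_filament(int c, int monomers, bool denovo_flag) {
    int f = alloc_fil();
    EFil& fl = fils[f];
    fl.alive = true;
    fl.denovo = denovo_flag;
    fl.offspring = denovo_flag;  // Arp-capped minus end: not removable
    fl.nb = 2;
    fl.tip_monomers = monomers;
    fl.x.resize(6);
    int cx = c % nx, cy = c / nx;
    double zmargin = std::min(50.0, mpar.Lz / 4);
    double p0[3] = {(cx + unif(rng)) * h, (cy + unif(rng)) * h,
                    zmargin + unif(rng) * (mpar.Lz - 2 * zmargin)};
    double zc = 2 * unif(rng) - 1;
    double phi = 2 * M_PI * unif(rng);
    double sxy = std::sqrt(std::max(0.0, 1 - zc * zc));
    double dir[3] = {sxy * std::cos(phi), sxy * std::sin(phi), zc};
    for (int m = 0; m < 3; ++m) {
      fl.x[m] = p0[m];
      fl.x[3 + m] = p0[m] + L_MON * monomers * dir[m];
    }
    tip_update(f);
    site_positions_update(f);
    redraw(chan_poly(f));
    redraw(chan_depoly(f));
    mark_dirty(f);
    fl.mark(0, fl.nb);
    return f;
  }

  void ev_nucleate(int c) {
    ArpA[c] -= 1;
    G[c] -= 1;
    spawn_filament(c, 1, true);
    refresh(chan_br(c));
    refresh(chan_nuc(c));
    if (c_spont > 0) refresh(chan_spont(c));
    refresh(chan_hopG(c));
    for (int ff : tip_fils[c]) refresh(chan_poly(ff));
    n_denovo += 1;
  }

  void ev_spont(int c) {
    G[c] -= 2;
    spawn_filament(c, 2, false);
    refresh(chan_br(c));
    refresh(chan_nuc(c));
    refresh(chan_spont(c));
    refresh(chan_hopG(c));
    for (int ff : tip_fils[c]) refresh(chan_poly(ff));
    n_spont += 1;
  }

  void execute(int id) {
    if (id < C) { t = ipq.key(id); redraw(id); ev_activate(id); }
    else if (id < 2 * C) { t = ipq.key(id); int c = id - C; redraw(id); ev_branch(c); }
    else if (id < 3 * C) {
      t = ipq.key(id);
      int c = id - 2 * C;
      redraw(id);
      ev_hop(G, c, true);
    } else if (id < 4 * C) {
      t = ipq.key(id);
      int c = id - 3 * C;
      redraw(id);
      ev_hop(ArpI, c, false);
    } else if (id < 5 * C) {
      t = ipq.key(id);
      int c = id - 4 * C;
      redraw(id);
      ev_nucleate(c);
    } else if (id < 6 * C) {
      t = ipq.key(id);
      int c = id - 5 * C;
      redraw(id);
      ev_spont(c);
    } else {
      t = ipq.key(id);
      int k = id - 6 * C;
      if (k % 2 == 0) ev_poly(k / 2); else ev_depoly(k / 2);
    }
    n_events += 1;
  }

  // ---- mechanics coupling ----
  struct SysMap {
    MechSystem sys;
    std::vector<int> fil_of_slot;   // filament per bead-offset block
    std::vector<int> offset;        // per filament
  };

  SysMap build_system(bool reduced) {
    SysMap sm;
    sm.offset.assign(n_fils_alloc, -1);
    int nb_total = 0;
    for (int f = 0; f < n_fils_alloc; ++f)
      if (fils[f].alive) { sm.offset[f] = nb_total; nb_total += fils[f].nb; }
    MechSystem& sys = sm.sys;
    sys.n = nb_total;
    sys.x.resize(3 * nb_total);
    sys.mobile.assign(nb_total, reduced ? 0 : 1);
    sys.reduced = reduced;
    for (int f = 0; f < n_fils_alloc; ++f) {
      if (!fils[f].alive) continue;
      EFil& fl = fils[f];
      int off = sm.offset[f];
      std::copy(fl.x.begin(), fl.x.end(), sys.x.begin() + 3 * off);
      for (int i = 0; i + 1 < fl.nb; ++i) {
        sys.seg_a.push_back(off + i);
        sys.seg_b.push_back(off + i + 1);
        sys.seg_fil.push_back(f);
        sys.seg_idx.push_back(i);
        sys.seg_rest.push_back(i + 2 == fl.nb ? L_MON * fl.tip_monomers : L_CYL);
      }
      if (reduced && fl.mob_lo >= 0) {
        for (int i = std::max(0, fl.mob_lo); i < std::min(fl.nb, fl.mob_hi); ++i)
          sys.mobile[off + i] = 1;
      }
    }
    for (const BondRec& br : bonds) {
      if (!fils[br.parent].alive || !fils[br.child].alive) continue;
      EFil& par = fils[br.parent];
      int nseg = par.nb - 1;
      int k = std::min((int)std::floor(br.arc / L_CYL), nseg - 1);
      double frac = std::max(0.0, std::min(1.0, (br.arc - L_CYL * k) / L_CYL));
      sys.bonds.push_back({sm.offset[br.parent] + k, sm.offset[br.parent] + k + 1,
                           frac, sm.offset[br.child], sm.offset[br.child] + 1,
                           mpar.L0_bond});
    }
    return sm;
  }

  // Local relaxation of one event-touched filament: a small subsystem of
  // its own beads (mobile in the dirty range), frozen branch-bond partner
  // beads, and frozen ghost segments of other filaments near the mobile
  // region (for excluded volume). Frozen-frozen terms are constant, so
  // lowering the subsystem energy lowers the total energy.
  void relax_fil_local(int f) {
    EFil& fl = fils[f];
    if (!fl.alive || fl.mob_lo < 0) return;
    MechSystem sys;
    sys.reduced = true;
    auto add_bead = [&](const double* p, bool mob) {
      sys.x.insert(sys.x.end(), p, p + 3);
      sys.mobile.push_back(mob ? 1 : 0);
      return sys.n++;
    };
    int nb = fl.nb;
    std::vector<int> own(nb);
    for (int i = 0; i < nb; ++i)
      own[i] = add_bead(&fl.x[3 * i], i >= fl.mob_lo && i < fl.mob_hi);
    for (int i = 0; i + 1 < nb; ++i) {
      sys.seg_a.push_back(own[i]);
      sys.seg_b.push_back(own[i + 1]);
      sys.seg_fil.push_back(0);
      sys.seg_idx.push_back(i);
      sys.seg_rest.push_back(i + 2 == nb ? L_MON * fl.tip_monomers : L_CYL);
    }
    for (const BondRec& br : bonds) {
      if (br.parent != f && br.child != f) continue;
      if (!fils[br.parent].alive || !fils[br.child].alive) continue;
      EFil& par = fils[br.parent];
      EFil& ch = fils[br.child];
      int nsegp = par.nb - 1;
      int k = std::min((int)std::floor(br.arc / L_CYL), nsegp - 1);
      double frac = std::max(0.0, std::min(1.0, (br.arc - L_CYL * k) / L_CYL));
      int a, b, c, d;
      if (br.parent == f) { a = own[k]; b = own[k + 1]; }
      else {
        a = add_bead(&par.x[3 * k], false);
        b = add_bead(&par.x[3 * (k + 1)], false);
      }
      if (br.child == f) { c = own[0]; d = own[1]; }
      else {
        c = add_bead(&ch.x[0], false);
        d = add_bead(&ch.x[3], false);
      }
      sys.bonds.push_back({a, b, frac, c, d, mpar.L0_bond});
    }
    // excluded-volume ghosts near the mobile region
    double blo[3], bhi[3];
    for (int m = 0; m < 3; ++m) {
      blo[m] = std::numeric_limits<double>::infinity();
      bhi[m] = -blo[m];
    }
    for (int i = std::max(0, fl.mob_lo); i < std::min(nb, fl.mob_hi); ++i)
      for (int m = 0; m < 3; ++m) {
        blo[m] = std::min(blo[m], fl.x[3 * i + m]);
        bhi[m] = std::max(bhi[m], fl.x[3 * i + m]);
      }
    double margin = mpar.ev_cut + L_SEG_MARGIN;
    for (int m = 0; m < 3; ++m) { blo[m] -= margin; bhi[m] += margin; }
    for (int g = 0; g < n_fils_alloc; ++g) {
      if (g == f || !fils[g].alive) continue;
      EFil& fg = fils[g];
      for (int i = 0; i + 1 < fg.nb; ++i) {
        bool in = true;
        for (int m = 0; m < 3 && in; ++m) {
          double lo = std::min(fg.x[3 * i + m], fg.x[3 * (i + 1) + m]);
          double hi = std::max(fg.x[3 * i + m], fg.x[3 * (i + 1) + m]);
          if (hi < blo[m] || lo > bhi[m]) in = false;
        }
        if (!in) continue;
        int va = add_bead(&fg.x[3 * i], false);
        int vb = add_bead(&fg.x[3 * (i + 1)], false);
        sys.seg_a.push_back(va);
        sys.seg_b.push_back(vb);
        sys.seg_fil.push_back(g + 1);
        sys.seg_idx.push_back(i);
        sys.seg_rest.push_back(i + 2 == fg.nb ? L_MON * fg.tip_monomers : L_CYL);
      }
    }
    MinimizeResult res = cg_minimize(sys, mpar, cg_tol, cg_max_iter, false);
    if (res.failed)
      stop("mechanics failure at t = %.4f s: non-finite energy", t);
    minimize_calls += 1;
    minimize_iters += res.iters;
    for (int i = 0; i < nb; ++i)
      std::copy(sys.x.begin() + 3 * own[i], sys.x.begin() + 3 * own[i] + 3,
                fl.x.begin() + 3 * i);
  }

  double relax(bool full) {
    if (!full && dirty_list.empty()) return NA_REAL;
    if (!full) {
      for (int f : dirty_list) relax_fil_local(f);
      for (int f : dirty_list) {
        if (!fils[f].alive) continue;
        site_positions_update(f);
        tip_update(f);
        ratchet_update(f);
      }
      clear_dirty();
      return NA_REAL;
    }
    SysMap sm = build_system(false);
    if (sm.sys.n == 0) { clear_dirty(); return 0.0; }
    MinimizeResult res = cg_minimize(sm.sys, mpar, cg_tol, cg_max_iter, false);
    if (res.failed)
      stop("mechanics failure at t = %.4f s: non-finite energy", t);
    minimize_calls += 1;
    minimize_iters += res.iters;
    for (int f = 0; f < n_fils_alloc; ++f) {
      if (!fils[f].alive) continue;
      EFil& fl = fils[f];
      int off = sm.offset[f];
      std::copy(sm.sys.x.begin() + 3 * off, sm.sys.x.begin() + 3 * (off + fl.nb),
                fl.x.begin());
      site_positions_update(f);
      tip_update(f);
      ratchet_update(f);
    }
    clear_dirty();
    sm.sys.reduced = false;
    sm.sys.mobile.clear();
    return system_energy(sm.sys, mpar).total();
  }

  void clear_dirty() {
    for (int f : dirty_list) { fils[f].mob_lo = fils[f].mob_hi = -1; }
    dirty_list.clear();
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_dendritic(IntegerMatrix nwasp_counts, List config, int seed) {
  Engine en;
  en.nx = as<int>(config["nx"]);
  en.ny = as<int>(config["ny"]);
  en.C = en.n_comp = en.nx * en.ny;
  en.h = as<double>(config["compartment_edge"]);
  double zh = as<double>(config["slab_height"]);
  double vr_l = en.h * en.h * zh * 1e-24;
  const double NA_CONST = 6.02214076e23;
  auto meso2 = [&](double k_um) { return k_um * 1e6 / (NA_CONST * vr_l); };
  en.c_act = as<double>(config["k_act"]) > 0 ? meso2(as<double>(config["k_act"])) : 0.0;
  en.c_br = as<double>(config["k_branch"]) > 0 ? meso2(as<double>(config["k_branch"])) : 0.0;
  en.c_poly = meso2(as<double>(config["k_poly"]));
  en.k_dep = as<double>(config["k_depoly"]);
  en.c_nuc = as<double>(config["k_nucleate"]) > 0
    ? meso2(as<double>(config["k_nucleate"])) : 0.0;
  bool spont_on = as<bool>(config["spontaneous_nucleation"]);
  en.c_spont = (spont_on && as<double>(config["k_spont"]) > 0)
    ? meso2(as<double>(config["k_spont"])) : 0.0;
  double D = as<double>(config["D"]);  // um^2/s
  double h_um = en.h / 1000.0;
  en.hopG_rate = en.hopA_rate = D / (h_um * h_um);
  en.t_end = as<double>(config["t_end"]);
  en.dt_mech = as<double>(config["dt_mech"]);
  en.snap_dt = as<double>(config["snapshot_dt"]);
  en.full_relax_dt = config.containsElementNamed("full_relax_dt")
    ? as<double>(config["full_relax_dt"]) : 10.0;
  en.ratchet_F0 = as<double>(config["F0"]);
  en.cg_tol = as<double>(config["cg_tol"]);
  en.cg_max_iter = as<int>(config["cg_max_iter"]);
  List mp = config["mech"];
  en.mpar.k_str = mp["k_str"];
  en.mpar.k_bend = mp["k_bend"];
  en.mpar.kvol = mp["kvol"];
  en.mpar.eps_b = mp["eps_boundary"];
  en.mpar.lambda = mp["lambda"];
  en.mpar.Lx = en.nx * en.h;
  en.mpar.Ly = en.ny * en.h;
  en.mpar.Lz = zh;
  en.mpar.ev_cut = mp["ev_cutoff"];
  en.mpar.rmin = mp["rmin"];
  en.mpar.k_bstr = mp["k_branch_str"];
  en.mpar.k_bb1 = mp["k_branch_bend1"];
  en.mpar.k_bb2 = mp["k_branch_bend2"];
  en.mpar.k_bdih = mp["k_branch_dihedral"];
  en.mpar.theta_branch = mp["theta_branch"];
  en.mpar.L0_bond = mp["L0_bond"];
  en.mpar.nquad = mp["nquad"];
  en.ratchet_range = 3.0 * en.mpar.lambda;

  // initial species
  long long g_total = as<double>(config["g_actin_copies"]);
  long long arp_total = as<double>(config["arp_copies"]);
  en.G.assign(en.C, 0); en.ArpI.assign(en.C, 0); en.ArpA.assign(en.C, 0);
  en.NW.assign(en.C, 0);
  // uniform deterministic split
  for (int c = 0; c < en.C; ++c) en.G[c] = g_total / en.C;
  for (long long r = 0; r < g_total % en.C; ++r) en.G[r] += 1;
  for (int c = 0; c < en.C; ++c) en.ArpI[c] = arp_total / en.C;
  for (long long r = 0; r < arp_total % en.C; ++r) en.ArpI[r] += 1;
  if (nwasp_counts.nrow() != en.ny || nwasp_counts.ncol() != en.nx)
    stop("nwasp_counts must be ny x nx");
  for (int cy = 0; cy < en.ny; ++cy)
    for (int cx = 0; cx < en.nx; ++cx)
      en.NW[cx + en.nx * cy] = nwasp_counts(cy, cx);

  en.nbr.assign(4 * en.C, -1);
  for (int c = 0; c < en.C; ++c) {
    int cx = c % en.nx, cy = c / en.nx;
    if (cx > 0) en.nbr[4 * c + 0] = c - 1;
    if (cx < en.nx - 1) en.nbr[4 * c + 1] = c + 1;
    if (cy > 0) en.nbr[4 * c + 2] = c - en.nx;
    if (cy < en.ny - 1) en.nbr[4 * c + 3] = c + en.nx;
  }
  en.n_nbr.assign(en.C, 0);
  for (int c = 0; c < en.C; ++c)
    for (int d = 0; d < 4; ++d)
      if (en.nbr[4 * c + d] >= 0) en.n_nbr[c] += 1;

  int n_seeds = as<int>(config["n_seeds"]);
  int seed_segments = as<int>(config["seed_segments"]);
  en.max_fils = n_seeds + (int)arp_total + 8;
  if (en.c_spont > 0) en.max_fils += 4096;
  en.fils.assign(en.max_fils, EFil());
  en.S.assign(en.C, 0);
  en.tip_fils.assign(en.C, {});
  en.rng.seed(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 11ULL);

  en.a_cache.assign(en.n_chan(), 0.0);
  en.ipq.init(en.n_chan());

  // seed filaments: random positions/orientations, straight, seed_segments
  // full segments
  double margin = 100.0;
  for (int sdi = 0; sdi < n_seeds; ++sdi) {
    int f = en.alloc_fil();
    EFil& fl = en.fils[f];
    fl.alive = true;
    fl.offspring = false;
    fl.nb = seed_segments + 1;
    fl.tip_monomers = 10;
    fl.x.resize(3 * fl.nb);
    double p0[3] = {margin + en.unif(en.rng) * (en.mpar.Lx - 2 * margin),
                    margin + en.unif(en.rng) * (en.mpar.Ly - 2 * margin),
                    margin + en.unif(en.rng) * (en.mpar.Lz - 2 * margin)};
    // isotropic direction
    double zc = 2 * en.unif(en.rng) - 1;
    double phi = 2 * M_PI * en.unif(en.rng);
    double sxy = std::sqrt(std::max(0.0, 1 - zc * zc));
    double dir[3] = {sxy * std::cos(phi), sxy * std::sin(phi), zc};
    for (int i = 0; i < fl.nb; ++i)
      for (int m = 0; m < 3; ++m)
        fl.x[3 * i + m] = p0[m] + i * L_CYL * dir[m];
    fl.tip_comp = -1;
  }

  // initialize channels
  for (int id = 0; id < en.n_chan(); ++id) {
    en.a_cache[id] = 0.0;
    en.ipq.update(id, std::numeric_limits<double>::infinity());
  }
  for (int f = 0; f < en.n_fils_alloc; ++f) {
    if (!en.fils[f].alive) continue;
    en.tip_update(f);
    en.site_positions_update(f);
    en.ratchet_update(f);
  }
  en.t = 0;
  for (int id = 0; id < en.n_chan(); ++id) {
    en.a_cache[id] = en.prop(id);
    en.ipq.update(id, en.draw_tau(en.a_cache[id]));
  }

  // snapshots
  std::vector<double> snap_t, snap_E;
  std::vector<long long> snap_G, snap_ArpI, snap_ArpA, snap_fil, snap_bond,
      snap_polymer, snap_denovo;
  auto record = [&](double tt, double E) {
    snap_t.push_back(tt);
    long long g = 0, ai = 0, aa = 0, mono = 0, nf = 0;
    for (int c = 0; c < en.C; ++c) { g += en.G[c]; ai += en.ArpI[c]; aa += en.ArpA[c]; }
    for (int f = 0; f < en.n_fils_alloc; ++f)
      if (en.fils[f].alive) { nf += 1; mono += en.fils[f].monomers(); }
    snap_G.push_back(g); snap_ArpI.push_back(ai); snap_ArpA.push_back(aa);
    snap_fil.push_back(nf); snap_bond.push_back((long long)en.bonds.size());
    snap_polymer.push_back(mono);
    snap_denovo.push_back(en.n_denovo);
    snap_E.push_back(E);
  };

  // total mechanical energy without relaxing (one evaluation)
  auto full_energy = [&]() {
    Engine::SysMap sm = en.build_system(false);
    if (sm.sys.n == 0) return 0.0;
    return system_energy(sm.sys, en.mpar).total();
  };

  double E0 = en.relax(true);
  record(0.0, E0);
  double next_mech = en.dt_mech;
  double next_snap = en.snap_dt;
  double next_full = en.full_relax_dt;
  double max_events = as<double>(config["max_events"]);
  long long interrupt_ctr = 0;

  while (next_mech <= en.t_end + 1e-12) {
    for (;;) {
      int id = en.ipq.top();
      double tau = en.ipq.top_key();
      if (!std::isfinite(tau) || tau > next_mech || en.n_events >= max_events)
        break;
      en.execute(id);
      if (((++interrupt_ctr) & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    en.t = next_mech;
    // event-driven local relaxation each chemistry interval; global
    // relaxation on its own (coarser) cadence
    bool do_full = next_mech + 1e-9 >= next_full;
    double E = en.relax(do_full);
    if (do_full) next_full += en.full_relax_dt;
    if (next_mech + 1e-9 >= next_snap) {
      record(next_mech, do_full ? E : full_energy());
      next_snap += en.snap_dt;
    }
    if (en.n_events >= max_events) break;
    next_mech += en.dt_mech;
  }

  // final filament registry
  int nb_total = 0, n_alive = 0;
  for (int f = 0; f < en.n_fils_alloc; ++f)
    if (en.fils[f].alive) { nb_total += en.fils[f].nb; n_alive += 1; }
  NumericMatrix beads(nb_total, 3);
  IntegerVector bead_fil(nb_total);
  IntegerVector fil_id(n_alive), fil_nb(n_alive), fil_tipm(n_alive);
  LogicalVector fil_off(n_alive);
  int bi = 0, fi = 0;
  for (int f = 0; f < en.n_fils_alloc; ++f) {
    if (!en.fils[f].alive) continue;
    EFil& fl = en.fils[f];
    fil_id[fi] = f + 1; fil_nb[fi] = fl.nb; fil_tipm[fi] = fl.tip_monomers;
    fil_off[fi] = fl.offspring;
    ++fi;
    for (int i = 0; i < fl.nb; ++i) {
      for (int m = 0; m < 3; ++m) beads(bi, m) = fl.x[3 * i + m];
      bead_fil[bi] = f + 1;
      ++bi;
    }
  }
  int nbd = en.bonds.size();
  IntegerVector bond_parent(nbd), bond_child(nbd);
  NumericVector bond_arc(nbd);
  for (int i = 0; i < nbd; ++i) {
    bond_parent[i] = en.bonds[i].parent + 1;
    bond_child[i] = en.bonds[i].child + 1;
    bond_arc[i] = en.bonds[i].arc;
  }

  return List::create(
    _["times"] = NumericVector(snap_t.begin(), snap_t.end()),
    _["G"] = NumericVector(snap_G.begin(), snap_G.end()),
    _["Arp_inactive"] = NumericVector(snap_ArpI.begin(), snap_ArpI.end()),
    _["Arp_active"] = NumericVector(snap_ArpA.begin(), snap_ArpA.end()),
    _["n_filaments"] = NumericVector(snap_fil.begin(), snap_fil.end()),
    _["n_branches"] = NumericVector(snap_bond.begin(), snap_bond.end()),
    _["polymerized"] = NumericVector(snap_polymer.begin(), snap_polymer.end()),
    _["n_denovo"] = NumericVector(snap_denovo.begin(), snap_denovo.end()),
    _["energy"] = NumericVector(snap_E.begin(), snap_E.end()),
    _["beads"] = beads, _["bead_fil"] = bead_fil,
    _["fil_id"] = fil_id, _["fil_nb"] = fil_nb, _["fil_tip_monomers"] = fil_tipm,
    _["fil_is_offspring"] = fil_off,
    _["bond_parent"] = bond_parent, _["bond_child"] = bond_child,
    _["bond_arc"] = bond_arc,
    _["n_events"] = en.n_events,
    _["counts"] = List::create(
      _["activation"] = (double)en.n_act, _["branch"] = (double)en.n_branch,
      _["poly"] = (double)en.n_poly, _["depoly"] = (double)en.n_depoly,
      _["denovo"] = (double)en.n_denovo, _["spontaneous"] = (double)en.n_spont,
      _["hops"] = (double)en.n_hops, _["removed"] = (double)en.n_removed,
      _["minimize_calls"] = (double)en.minimize_calls,
      _["minimize_iters"] = (double)en.minimize_iters));
}
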
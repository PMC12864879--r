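#include <Rcpp.h>
#include "mechanics.h"

using namespace Rcpp;
using namespace curvmech;

MechParams parse_params(List p) {
  MechParams par;
  if (p.containsElementNamed("k_str")) par.k_str = p["k_str"];
  if (p.containsElementNamed("k_bend")) par.k_bend = p["k_bend"];
  if (p.containsElementNamed("kvol")) par.kvol = p["kvol"];
  if (p.containsElementNamed("eps_boundary")) par.eps_b = p["eps_boundary"];
  if (p.containsElementNamed("lambda")) par.lambda = p["lambda"];
  if (p.containsElementNamed("box")) {
    NumericVector b = p["box"];
    par.Lx = b[0]; par.Ly = b[1]; par.Lz = b[2];
  }
  if (p.containsElementNamed("ev_cutoff")) par.ev_cut = p["ev_cutoff"];
  if (p.containsElementNamed("rmin")) par.rmin = p["rmin"];
  if (p.containsElementNamed("k_branch_str")) par.k_bstr = p["k_branch_str"];
  if (p.containsElementNamed("k_branch_bend1")) par.k_bb1 = p["k_branch_bend1"];
  if (p.containsElementNamed("k_branch_bend2")) par.k_bb2 = p["k_branch_bend2"];
  if (p.containsElementNamed("k_branch_dihedral")) par.k_bdih = p["k_branch_dihedral"];
  if (p.containsElementNamed("theta_branch")) par.theta_branch = p["theta_branch"];
  if (p.containsElementNamed("L0_bond")) par.L0_bond = p["L0_bond"];
  if (p.containsElementNamed("nquad")) par.nquad = p["nquad"];
  return par;
}

MechSystem parse_system(NumericMatrix x, IntegerVector seg_a,
                        IntegerVector seg_b, IntegerVector seg_fil,
                        IntegerVector seg_idx, NumericVector seg_rest,
                        List bonds) {
  MechSystem sys;
  sys.n = x.nrow();
  sys.x.resize(3 * sys.n);
  for (int i = 0; i < sys.n; ++i)
    for (int m = 0; m < 3; ++m) sys.x[3 * i + m] = x(i, m);
  int ns = seg_a.size();
  for (int i = 0; i < ns; ++i) {
    sys.seg_a.push_back(seg_a[i] - 1);
    sys.seg_b.push_back(seg_b[i] - 1);
    sys.seg_fil.push_back(seg_fil[i]);
    sys.seg_idx.push_back(seg_idx[i]);
    sys.seg_rest.push_back(seg_rest[i]);
  }
  if (bonds.size() > 0) {
    IntegerVector ba = bonds["a"], bb = bonds["b"], bc = bonds["c"], bd = bonds["d"];
    NumericVector bs = bonds["s"], bl = bonds["L0"];
    for (int i = 0; i < ba.size(); ++i)
      sys.bonds.push_back({ba[i] - 1, bb[i] - 1, bs[i], bc[i] - 1, bd[i] - 1,
                           bl[i]});
  }
  return sys;
}

// [[Rcpp::export]]
List cpp_mech_terms(NumericMatrix x, IntegerVector seg_a, IntegerVector seg_b,
                    IntegerVector seg_fil, IntegerVector seg_idx,
                    NumericVector seg_rest, List bonds, List params) {
  MechSystem sys = parse_system(x, seg_a, seg_b, seg_fil, seg_idx, seg_rest, bonds);
  MechParams par = parse_params(params);
  EnergyTerms E = system_energy(sys, par);
  return List::create(
    _["stretch"] = E.stretch, _["bend"] = E.bend, _["excluded"] = E.excl,
    _["boundary"] = E.boundary, _["branch_stretch"] = E.b_str,
    _["branch_bend_I"] = E.b_bend1, _["branch_bend_II"] = E.b_bend2,
    _["branch_dihedral"] = E.b_dih, _["total"] = E.total());
}

// [[Rcpp::export]]
NumericMatrix cpp_mech_grad(NumericMatrix x, IntegerVector seg_a,
                            IntegerVector seg_b, IntegerVector seg_fil,
                            IntegerVector seg_idx, NumericVector seg_rest,
                            List bonds, List params) {
  MechSystem sys = parse_system(x, seg_a, seg_b, seg_fil, seg_idx, seg_rest, bonds);
  MechParams par = parse_params(params);
  std::vector<double> g;
  system_grad(sys, par, g);
  NumericMatrix out(sys.n, 3);
  for (int i = 0; i < sys.n; ++i)
    for (int m = 0; m < 3; ++m) out(i, m) = g[3 * i + m];
  return out;
}

// [[Rcpp::export]]
List cpp_mech_minimize(NumericMatrix x, IntegerVector seg_a,
                       IntegerVector seg_b, IntegerVector seg_fil,
                       IntegerVector seg_idx, NumericVector seg_rest,
                       List bonds, List params, double tol, int max_iter) {
  MechSystem sys = parse_system(x, seg_a, seg_b, seg_fil, seg_idx, seg_rest, bonds);
  MechParams par = parse_params(params);
  MinimizeResult res = cg_minimize(sys, par, tol, max_iter, true);
  if (res.failed) stop("energy minimization failed: non-finite energy");
  NumericMatrix out(sys.n, 3);
  for (int i = 0; i < sys.n; ++i)
    for (int m = 0; m < 3; ++m) out(i, m) = sys.x[3 * i + m];
  return List::create(
    _["x"] = out, _["iters"] = res.iters, _["converged"] = res.converged,
    _["max_force"] = res.max_force,
    _["energy_trace"] = NumericVector(res.energy_trace.begin(),
                                      res.energy_trace.end()));
}

// [[Rcpp::export]]
double cpp_ev_pair_energy(NumericVector p0, NumericVector p1, NumericVector q0,
                          NumericVector q1, double kvol, int nquad,
                          double rmin) {
  return ev_pair_energy(&p0[0], &p1[0], &q0[0], &q1[0], kvol, nquad, rmin);
}
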
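// Generic compartmental stochastic kinetics via the next-reaction method
// (Gibson & Bruck): per-channel tentative firing times held in an indexed
// priority queue, dependency-graph propensity updates, diffusion as hopping
// between 4-neighbour lattice compartments with reflecting boundaries.

#include <Rcpp.h>
#include <random>
#include "ipq.h"

using namespace Rcpp;

namespace {

struct Channel {
  // type 0: reaction (rx in compartment comp)
  // type 1: hop of species sp from comp to comp2
  int type, rx, sp, comp, comp2;
  double a;  // cached propensity
};

struct Net {
  int n_sp, nx, ny, n_comp;
  std::vector<std::vector<std::pair<int,int>>> re, pr; // (species, stoich)
  std::vector<double> c_meso;
  std::vector<double> hop_rate;            // per species, per neighbour
  std::vector<long long> counts;           // sp + n_sp * comp
  std::vector<Channel> chan;
  std::vector<std::vector<int>> dep;       // (sp,comp) -> channel ids
  IndexedPriorityQueue ipq;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  double t = 0.0;

  long long cnt(int sp, int comp) const { return counts[sp + n_sp * comp]; }

  double prop(const Channel& ch) const {
    if (ch.type == 1) return hop_rate[ch.sp] * cnt(ch.sp, ch.comp);
    double a = c_meso[ch.rx];
    for (auto& rs : re[ch.rx]) {
      long long n = cnt(rs.first, ch.comp);
      if (rs.second == 1) a *= n;
      else if (rs.second == 2) a *= 0.5 * n * (n - 1);
      else stop("reactant stoichiometry > 2 not supported");
      if (n < rs.second) return 0.0;
    }
    return a > 0 ? a : 0.0;
  }

  double draw_tau(double a) {
    if (a <= 0) return std::numeric_limits<double>::infinity();
    double r = unif(rng);
    while (r <= 0.0 || r >= 1.0) r = unif(rng);
    return t + std::log(1.0 / r) / a;
  }

  // Gibson-Bruck rescale for an unfired channel whose propensity changed.
  void refresh(int id) {
    Channel& ch = chan[id];
    double a_new = prop(ch);
    double a_old = ch.a;
    if (a_new == a_old) return;
    double tau_old = ipq.key(id), tau_new;
    if (a_new <= 0) {
      tau_new = std::numeric_limits<double>::infinity();
    } else if (a_old <= 0 || !std::isfinite(tau_old)) {
      tau_new = draw_tau(a_new);
    } else {
      tau_new = t + (a_old / a_new) * (tau_old - t);
    }
    ch.a = a_new;
    ipq.update(id, tau_new);
  }
};

int neighbour(int comp, int dir, int nx, int ny) {
  int x = comp % nx, y = comp / nx;
  switch (dir) {
    case 0: x -= 1; break;
    case 1: x += 1; break;
    case 2: y -= 1; break;
    default: y += 1; break;
  }
  if (x < 0 || x >= nx || y < 0 || y >= ny) return -1;  // reflecting
  return x + nx * y;
}

} // namespace

// [[Rcpp::export]]
List cpp_nrm_run(IntegerMatrix counts0, List reactions, NumericVector hop_rates,
                 int nx, int ny, double t_end, NumericVector save_times,
                 int seed, double max_events, bool record_events,
                 int max_record) {
  Net net;
  net.n_sp = counts0.nrow();
  net.nx = nx; net.ny = ny; net.n_comp = nx * ny;
  if (counts0.ncol() != net.n_comp) stop("counts0 must have nx*ny columns");
  net.counts.assign(net.n_sp * net.n_comp, 0);
  for (int c = 0; c < net.n_comp; ++c)
    for (int s = 0; s < net.n_sp; ++s)
      net.counts[s + net.n_sp * c] = counts0(s, c);

  int n_rx = reactions.size();
  net.re.resize(n_rx); net.pr.resize(n_rx); net.c_meso.resize(n_rx);
  for (int r = 0; r < n_rx; ++r) {
    List rx = reactions[r];
    IntegerVector rsp = rx["re_sp"], rst = rx["re_st"];
    IntegerVector psp = rx["pr_sp"], pst = rx["pr_st"];
    for (int i = 0; i < rsp.size(); ++i)
      net.re[r].push_back({rsp[i] - 1, rst[i]});
    for (int i = 0; i < psp.size(); ++i)
      net.pr[r].push_back({psp[i] - 1, pst[i]});
    net.c_meso[r] = as<double>(rx["c_meso"]);
  }
  net.hop_rate.assign(hop_rates.begin(), hop_rates.end());
  if ((int)net.hop_rate.size() != net.n_sp) stop("hop_rates length mismatch");

  // Build channels
  for (int c = 0; c < net.n_comp; ++c)
    for (int r = 0; r < n_rx; ++r)
      net.chan.push_back({0, r, -1, c, -1, 0.0});
  for (int s = 0; s < net.n_sp; ++s) {
    if (net.hop_rate[s] <= 0) continue;
    for (int c = 0; c < net.n_comp; ++c)
      for (int d = 0; d < 4; ++d) {
        int c2 = neighbour(c, d, nx, ny);
        if (c2 >= 0) net.chan.push_back({1, -1, s, c, c2, 0.0});
      }
  }
  int n_chan = net.chan.size();

  // Dependency graph: (species, compartment) -> channels whose propensity
  // depends on that count.
  net.dep.assign(net.n_sp * net.n_comp, {});
  for (int id = 0; id < n_chan; ++id) {
    Channel& ch = net.chan[id];
    if (ch.type == 1) {
      net.dep[ch.sp + net.n_sp * ch.comp].push_back(id);
    } else {
      for (auto& rs : net.re[ch.rx])
        net.dep[rs.first + net.n_sp * ch.comp].push_back(id);
    }
  }

  net.rng.seed(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);
  net.ipq.init(n_chan);
  for (int id = 0; id < n_chan; ++id) {
    net.chan[id].a = net.prop(net.chan[id]);
    net.ipq.update(id, net.draw_tau(net.chan[id].a));
  }

  int n_save = save_times.size();
  NumericMatrix saved(net.n_sp * net.n_comp, n_save);
  int save_i = 0;
  std::vector<double> ev_times;
  std::vector<int> ev_chan_type;
  if (record_events) { ev_times.reserve(max_record); ev_chan_type.reserve(max_record); }

  double n_events = 0;
  auto flush_saves = [&](double upto) {
    while (save_i < n_save && save_times[save_i] <= upto) {
      for (int k = 0; k < net.n_sp * net.n_comp; ++k)
        saved(k, save_i) = (double)net.counts[k];
      ++save_i;
    }
  };

  std::vector<int> touched;
  for (;;) {
    int id = net.ipq.top();
    double tau = net.ipq.top_key();
    if (!std::isfinite(tau) || tau > t_end || n_events >= max_events) break;
    flush_saves(tau);
    net.t = tau;
    Channel& ch = net.chan[id];
    touched.clear();
    if (ch.type == 1) {
      net.counts[ch.sp + net.n_sp * ch.comp] -= 1;
      net.counts[ch.sp + net.n_sp * ch.comp2] += 1;
      touched.push_back(ch.sp + net.n_sp * ch.comp);
      touched.push_back(ch.sp + net.n_sp * ch.comp2);
    } else {
      for (auto& rs : net.re[ch.rx]) {
        net.counts[rs.first + net.n_sp * ch.comp] -= rs.second;
        if (net.counts[rs.first + net.n_sp * ch.comp] < 0)
          stop("internal consistency error: negative count");
        touched.push_back(rs.first + net.n_sp * ch.comp);
      }
      for (auto& ps : net.pr[ch.rx]) {
        net.counts[ps.first + net.n_sp * ch.comp] += ps.second;
        touched.push_back(ps.first + net.n_sp * ch.comp);
      }
    }
    // fired channel: fresh draw
    ch.a = net.prop(ch);
    net.ipq.update(id, net.draw_tau(ch.a));
    // dependency-graph neighbours: rescale
    for (int key : touched)
      for (int dep_id : net.dep[key])
        if (dep_id != id) net.refresh(dep_id);
    n_events += 1;
    if (record_events && (int)ev_times.size() < max_record) {
      ev_times.push_back(net.t);
      ev_chan_type.push_back(ch.type);
    }
  }
  flush_saves(t_end);
  // propensity cache coherence check (cheap, catches bookkeeping bugs)
  double max_rel = 0;
  for (int id = 0; id < n_chan; ++id) {
    double a = net.prop(net.chan[id]);
    double d = std::abs(a - net.chan[id].a);
    double rel = d / std::max(1.0, std::abs(a));
    if (rel > max_rel) max_rel = rel;
  }

  return List::create(
    _["counts"] = saved,
    _["save_times"] = save_times,
    _["t_final"] = net.t,
    _["n_events"] = n_events,
    _["event_times"] = NumericVector(ev_times.begin(), ev_times.end()),
    _["event_types"] = IntegerVector(ev_chan_type.begin(), ev_chan_type.end()),
    _["propensity_max_rel_err"] = max_rel);
}
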
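// Event-driven exact stochastic simulation of the birth-death-mutation
// model of B-cell affinity maturation. Each live cell i carries a scalar
// fitness w_i; birth and death rates are Hill-modulated and normalised by
// the population means so that <lambda_i> = lambda0 and
// <delta_i> = delta0 + (lambda0 - delta0) M / C at every recomputation.
// Scenarios: 0 = no_selection, 1 = lung_no_decay, 2 = lung (growth decay
// after T_dec), 3 = lymph_node (dark/light-zone shuttling with frozen
// per-cell rates between zone transitions).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  int scenario;
  double lambda0, delta0, D, g_lambda, g_delta, h, C;
  int n_founders;
  double T_g, T_end, T_dec, kappa, k12, k21, alpha_LN;
  int cap_mode;  // 0 auto, 1 baseline, 2 effective
  int max_cells;
  double record_dt;
  bool log_events;
};

struct State {
  std::vector<double> w, lam, del;
  std::vector<int> clone, zone;  // zone: -1 none, 0 DZ, 1 LZ
  double Sfl = 0, Sfd = 0, SB = 0, SD = 0;
  int nDZ = 0;
};

inline double f_lam(double w, const Params& p) {
  double wh = std::pow(w, p.h);
  return 1.0 + (p.g_lambda - 1.0) * wh / (1.0 + wh);
}
inline double f_del(double w, const Params& p) {
  double wh = std::pow(w, p.h);
  return (1.0 + wh) / (1.0 + p.g_delta * wh);
}

// effective average birth rate at time t (lung decay scenario)
inline double eff_lambda0(double t, const Params& p) {
  if (p.scenario == 2 && t > p.T_dec) {
    return (p.lambda0 - p.delta0) * std::exp(-p.kappa * (t - p.T_dec)) +
           p.delta0;
  }
  if (p.scenario == 3) return p.alpha_LN * p.lambda0;
  return p.lambda0;
}

// lambda0 entering the capacity term (lambda0 - delta0) M / C. "auto"
// uses the alpha-boosted rate in the lymph-node scenario (the modified
// rate replaces lambda0 throughout the formalism there) but keeps the
// baseline during the growth phase and under lung growth decay.
inline double cap_lambda0(double t, const Params& p) {
  bool post = t >= p.T_g;
  if (p.cap_mode == 1) return p.lambda0;
  if (p.cap_mode == 2) return post ? eff_lambda0(t, p) : p.lambda0;
  return (p.scenario == 3 && post) ? p.alpha_LN * p.lambda0 : p.lambda0;
}

void refresh_sums(State& s, const Params& p) {
  s.Sfl = s.Sfd = s.SB = s.SD = 0;
  s.nDZ = 0;
  for (size_t i = 0; i < s.w.size(); ++i) {
    s.Sfl += f_lam(s.w[i], p);
    s.Sfd += f_del(s.w[i], p);
    s.SB += s.lam[i];
    s.SD += s.del[i];
    if (s.zone[i] == 0) ++s.nDZ;
  }
}

void remove_cell(State& s, const Params& p, int i) {
  s.Sfl -= f_lam(s.w[i], p);
  s.Sfd -= f_del(s.w[i], p);
  s.SB -= s.lam[i];
  s.SD -= s.del[i];
  if (s.zone[i] == 0) --s.nDZ;
  int last = (int)s.w.size() - 1;
  s.w[i] = s.w[last]; s.lam[i] = s.lam[last]; s.del[i] = s.del[last];
  s.clone[i] = s.clone[last]; s.zone[i] = s.zone[last];
  s.w.pop_back(); s.lam.pop_back(); s.del.pop_back();
  s.clone.pop_back(); s.zone.pop_back();
}

void add_cell(State& s, const Params& p, double w, int clone, int zone,
              double lam, double del) {
  s.w.push_back(w); s.clone.push_back(clone); s.zone.push_back(zone);
  s.lam.push_back(lam); s.del.push_back(del);
  s.Sfl += f_lam(w, p);
  s.Sfd += f_del(w, p);
  s.SB += lam; s.SD += del;
  if (zone == 0) ++s.nDZ;
}

// index of the cell selected with probability proportional to weight[i]
int pick_weighted(const std::vector<double>& weight, double total) {
  double u = unif_rand() * total, acc = 0;
  int n = (int)weight.size();
  for (int i = 0; i < n; ++i) {
    acc += weight[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

int pick_by_f(const State& s, const Params& p, bool birth) {
  double total = birth ? s.Sfl : s.Sfd, u = unif_rand() * total, acc = 0;
  int n = (int)s.w.size();
  for (int i = 0; i < n; ++i) {
    acc += birth ? f_lam(s.w[i], p) : f_del(s.w[i], p);
    if (u <= acc) return i;
  }
  return n - 1;
}

int pick_zone(const State& s, int zone, int count) {
  int M = (int)s.zone.size();
  if (4 * count >= M) {  // rejection sampling: O(1) expected
    for (;;) {
      int i = (int)std::floor(unif_rand() * M);
      if (i >= M) i = M - 1;
      if (s.zone[i] == zone) return i;
    }
  }
  int k = (int)std::floor(unif_rand() * count);
  if (k >= count) k = count - 1;
  int seen = 0;
  for (int i = 0; i < M; ++i) {
    if (s.zone[i] == zone) {
      if (seen == k) return i;
      ++seen;
    }
  }
  return M - 1;
}

inline double mutate_w(double w, const Params& p) {
  double v = w + norm_rand() * std::sqrt(2.0 * p.D);
  return v < 0 ? 0 : v;
}

}  // namespace

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(List cfg, NumericVector w0) {
  Params p;
  p.scenario = as<int>(cfg["scenario_code"]);
  p.lambda0 = as<double>(cfg["lambda0"]);
  p.delta0 = as<double>(cfg["delta0"]);
  p.D = as<double>(cfg["D"]);
  p.g_lambda = as<double>(cfg["g_lambda"]);
  p.g_delta = as<double>(cfg["g_delta"]);
  p.h = as<double>(cfg["h"]);
  p.C = as<double>(cfg["C"]);
  p.n_founders = as<int>(cfg["n_founders"]);
  p.T_g = as<double>(cfg["T_g"]);
  p.T_end = as<double>(cfg["T_end"]);
  p.T_dec = as<double>(cfg["T_dec"]);
  p.kappa = as<double>(cfg["kappa"]);
  p.k12 = as<double>(cfg["k_DZLZ"]);
  p.k21 = as<double>(cfg["k_LZDZ"]);
  p.alpha_LN = as<double>(cfg["alpha_LN"]);
  p.cap_mode = as<int>(cfg["cap_mode"]);
  p.max_cells = as<int>(cfg["max_cells"]);
  p.record_dt = as<double>(cfg["record_dt"]);
  p.log_events = as<bool>(cfg["log_events"]);

  State s;
  for (int i = 0; i < p.n_founders; ++i) {
    // founders start unzoned; rate caches refreshed at phase boundaries
    add_cell(s, p, w0[i], i, -1, p.lambda0, p.delta0);
  }

  std::vector<double> snap_t, snap_meanw, snap_dom;
  std::vector<int> snap_M, snap_nclones;
  std::vector<std::vector<int>> snap_sizes;
  std::vector<double> ev_t;
  std::vector<int> ev_type, ev_clone;

  double t = 0;
  double next_snap = 0;
  bool ln_active = false;
  bool extinct = false;
  long n_events = 0;

  auto take_snapshot = [&](double at) {
    std::vector<int> sizes(p.n_founders, 0);
    double sw = 0;
    for (size_t i = 0; i < s.w.size(); ++i) {
      sizes[s.clone[i]]++;
      sw += s.w[i];
    }
    int M = (int)s.w.size(), nc = 0, mx = 0;
    for (int c = 0; c < p.n_founders; ++c) {
      if (sizes[c] > 0) ++nc;
      if (sizes[c] > mx) mx = sizes[c];
    }
    snap_t.push_back(at);
    snap_M.push_back(M);
    snap_nclones.push_back(nc);
    snap_meanw.push_back(M ? sw / M : NA_REAL);
    snap_dom.push_back(M ? (double)mx / M : NA_REAL);
    snap_sizes.push_back(sizes);
  };

  auto activate_ln = [&]() {
    // assign zones from the stationary split and initialise frozen rates
    double p_dz = p.k21 / (p.k12 + p.k21);
    refresh_sums(s, p);
    int M = (int)s.w.size();
    double fbar_l = s.Sfl / M, fbar_d = s.Sfd / M;
    s.SB = s.SD = 0; s.nDZ = 0;
    for (int i = 0; i < M; ++i) {
      if (unif_rand() < p_dz) {
        s.zone[i] = 0; ++s.nDZ;
        s.lam[i] = p.alpha_LN * p.lambda0 * f_lam(s.w[i], p) / fbar_l;
        s.del[i] = p.delta0;
      } else {
        s.zone[i] = 1;
        s.lam[i] = 0;
        s.del[i] = p.delta0 * f_del(s.w[i], p) / fbar_d +
                   (cap_lambda0(p.T_g, p) - p.delta0) * M / p.C;
      }
      s.SB += s.lam[i]; s.SD += s.del[i];
    }
    ln_active = true;
  };

  refresh_sums(s, p);
  long since_refresh = 0;

  while (t < p.T_end) {
    int M = (int)s.w.size();
    if (M == 0) { extinct = true; break; }
    if (M > p.max_cells) stop("population exceeded max_cells (%d)", p.max_cells);

    bool selection_on = (t >= p.T_g) && p.scenario != 0;
    if (p.scenario == 3 && selection_on && !ln_active) activate_ln();

    double totB, totD, totT12 = 0, totT21 = 0;
    double l0 = eff_lambda0(t, p);
    double l0cap = cap_lambda0(t, p);
    if (!selection_on) {
      totB = p.lambda0 * M;
      totD = p.delta0 * M + (p.lambda0 - p.delta0) * M * (double)M / p.C;
    } else if (p.scenario == 3) {
      totB = s.SB;
      totD = s.SD;
      totT12 = p.k12 * s.nDZ;
      totT21 = p.k21 * (M - s.nDZ);
    } else {
      // conservation makes the totals exact whatever the fitness spread
      totB = l0 * M;
      totD = p.delta0 * M + (l0cap - p.delta0) * M * (double)M / p.C;
    }
    double R = totB + totD + totT12 + totT21;
    if (R <= 0) { t = p.T_end; break; }

    double tau = exp_rand() / R;
    double t_new = t + tau;

    // rate regime changes at T_g, T_dec and LN activation: advance to the
    // boundary and redraw (memorylessness of the exponential clock)
    double boundary = p.T_end;
    if (t < p.T_g && p.T_g < boundary) boundary = p.T_g;
    if (p.scenario == 2 && t < p.T_dec && p.T_dec < boundary)
      boundary = p.T_dec;
    if (t_new > boundary) {
      t = boundary;
      continue;
    }

    // thinning for the continuously decaying birth rate in the lung
    if (p.scenario == 2 && t >= p.T_dec && t >= p.T_g) {
      double l0n = eff_lambda0(t_new, p);
      double l0ncap = cap_lambda0(t_new, p);
      double totBn = l0n * M;
      double totDn = p.delta0 * M + (l0ncap - p.delta0) * M * (double)M / p.C;
      double Rn = totBn + totDn;
      if (unif_rand() > Rn / R) {  // no event; clock advances
        t = t_new;
        continue;
      }
      totB = totBn; totD = totDn; R = Rn;
    }

    while (next_snap <= t_new && next_snap <= p.T_end + 1e-12) {
      take_snapshot(next_snap);
      next_snap += p.record_dt;
    }
    t = t_new;
    ++n_events;

    double u = unif_rand() * R;
    int ev = -1, cell = -1;
    if (u < totB) {
      // birth
      if (!selection_on) {
        cell = (int)std::floor(unif_rand() * M);
        if (cell >= M) cell = M - 1;
      } else if (p.scenario == 3) {
        cell = pick_weighted(s.lam, s.SB);
      } else {
        cell = pick_by_f(s, p, true);
      }
      double wc = mutate_w(s.w[cell], p);
      double lam_c = p.lambda0, del_c = p.delta0;
      int zone_c = s.zone[cell];
      if (p.scenario == 3 && ln_active) {
        zone_c = 0;  // daughters are born in the dark zone
        lam_c = p.alpha_LN * p.lambda0 * f_lam(wc, p) / (s.Sfl / M);
        del_c = p.delta0;
      }
      add_cell(s, p, wc, s.clone[cell], zone_c, lam_c, del_c);
      ev = 0;
      if (p.log_events) {
        ev_t.push_back(t); ev_type.push_back(0);
        ev_clone.push_back(s.clone[cell]);
      }
    } else if (u < totB + totD) {
      // death: normalised Hill part selects by f_delta, capacity part
      // uniformly
      if (!selection_on) {
        cell = (int)std::floor(unif_rand() * M);
        if (cell >= M) cell = M - 1;
      } else if (p.scenario == 3) {
        cell = pick_weighted(s.del, s.SD);
      } else {
        double hill = p.delta0 * M;
        if (unif_rand() < hill / totD) {
          cell = pick_by_f(s, p, false);
        } else {
          cell = (int)std::floor(unif_rand() * M);
          if (cell >= M) cell = M - 1;
        }
      }
      if (p.log_events) {
        ev_t.push_back(t); ev_type.push_back(1);
        ev_clone.push_back(s.clone[cell]);
      }
      remove_cell(s, p, cell);
      ev = 1;
    } else if (u < totB + totD + totT12) {
      // DZ -> LZ: death rate refreshed, birth rate switched off
      cell = pick_zone(s, 0, s.nDZ);
      s.SB -= s.lam[cell]; s.SD -= s.del[cell];
      s.zone[cell] = 1; --s.nDZ;
      s.lam[cell] = 0;
      s.del[cell] = p.delta0 * f_del(s.w[cell], p) / (s.Sfd / M) +
                    (cap_lambda0(t, p) - p.delta0) * M / p.C;
      s.SB += s.lam[cell]; s.SD += s.del[cell];
      ev = 2;
      if (p.log_events) {
        ev_t.push_back(t); ev_type.push_back(2);
        ev_clone.push_back(s.clone[cell]);
      }
    } else {
      // LZ -> DZ: birth rate refreshed on re-entry
      cell = pick_zone(s, 1, M - s.nDZ);
      s.SB -= s.lam[cell]; s.SD -= s.del[cell];
      s.zone[cell] = 0; ++s.nDZ;
      s.lam[cell] = p.alpha_LN * p.lambda0 * f_lam(s.w[cell], p) /
                    (s.Sfl / M);
      s.del[cell] = p.delta0;
      s.SB += s.lam[cell]; s.SD += s.del[cell];
      ev = 3;
      if (p.log_events) {
        ev_t.push_back(t); ev_type.push_back(3);
        ev_clone.push_back(s.clone[cell]);
      }
    }
    (void)ev;

    if (++since_refresh >= 4096) {  // guard against floating-point drift
      refresh_sums(s, p);
      since_refresh = 0;
    }
  }

  while (next_snap <= p.T_end + 1e-12) {
    take_snapshot(next_snap);
    next_snap += p.record_dt;
  }

  int n_snap = (int)snap_t.size();
  IntegerMatrix sizes(n_snap, p.n_founders);
  for (int i = 0; i < n_snap; ++i)
    for (int c = 0; c < p.n_founders; ++c) sizes(i, c) = snap_sizes[i][c];

  List out = List::create(
    _["time"] = wrap(snap_t), _["M"] = wrap(snap_M),
    _["n_clones"] = wrap(snap_nclones), _["mean_w"] = wrap(snap_meanw),
    _["dominant_fraction"] = wrap(snap_dom), _["clone_sizes"] = sizes,
    _["final_w"] = wrap(s.w), _["final_clone"] = wrap(s.clone),
    _["final_zone"] = wrap(s.zone), _["extinct"] = extinct,
    _["n_events"] = (double)n_events);
  if (p.log_events) {
    out["event_log"] = DataFrame::create(
        _["t"] = wrap(ev_t), _["type"] = wrap(ev_type),
        _["clone"] = wrap(ev_clone));
  }
  return out;
}
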
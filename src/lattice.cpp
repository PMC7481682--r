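// Lattice Monte Carlo engines for clusters of molecular motors.
//
// Shared model: N motors tethered to one cargo walk on a 1D lattice with
// simple exclusion. The forwardmost bound motor (the leader) carries the
// whole dimensionless load f, reweighting its stepping rates by Boltzmann
// factors p1 = p e^{-f delta}, q1 = q e^{f (1-delta)}. Non-processive
// motors unbind (k_off) and rebind (k_on, attempt probability k_on dt per
// time step) inside a binding window:
//   scenario A: a fixed window of M sites whose left edge tracks the
//     rearmost bound motor. A binding attempt succeeds with probability
//     (M - n)/M -- the motor reaches for one of its M cargo-reach sites
//     at random and fails on the n occupied ones -- and the successful
//     binder lands uniformly on a free window site, so motor identities
//     may swap. This realizes the state-n binding rate
//     (N - n)(M - n) k_on / M of the limited-site master equation.
//   scenario B: the window spans the bound cluster plus one extra site
//     beyond each end, and a motor may only rebind on the (always free)
//     sites strictly between its nearest bound neighbours, extended by
//     the end sites, so the motor sequence along the filament is
//     preserved. The attempt succeeds whenever that interval is
//     non-empty, with the site drawn uniformly from it.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

enum Scenario { PROCESSIVE = 0, SCEN_A = 1, SCEN_B = 2 };

struct Engine {
  int N;
  double p, q, delta, kon, koff, f, dt;
  double p1, q1;
  int scenario;
  int M_fixed;

  std::vector<int> pos;      // lattice site per motor (stale if unbound)
  std::vector<char> bound;
  std::unordered_set<int> occ;
  int n_bound = 0;
  long long wl = 0, wr = 0;  // inclusive binding window

  // observables
  std::vector<double> episode_v;
  std::vector<double> episode_w;   // episode durations (s)
  std::vector<double> run_len;
  std::vector<double> occ_w;       // weight (steps or time) per n bound
  double window_w = 0.0;           // accumulated window size
  double meas_w = 0.0;             // accumulated measurement weight

  // episode bookkeeping
  int ep_leader = -1;
  double ep_t0 = 0.0;
  long long ep_x0 = 0;
  bool ep_measured = false;

  // run-length bookkeeping
  bool run_active = false;
  bool run_measured = false;
  long long run_x0 = 0;

  Engine(int N_, double p_, double q_, double delta_, double kon_,
         double koff_, double f_, double dt_, int scenario_, int M_fixed_)
      : N(N_), p(p_), q(q_), delta(delta_), kon(kon_), koff(koff_), f(f_),
        dt(dt_), scenario(scenario_), M_fixed(M_fixed_) {
    p1 = p * std::exp(-f * delta);
    q1 = q * std::exp(f * (1.0 - delta));
    pos.assign(N, 0);
    bound.assign(N, 0);
    occ_w.assign(N + 1, 0.0);
  }

  long long window_size() const { return wr - wl + 1; }

  int leader() const {  // forwardmost bound motor, -1 if none bound
    int best = -1;
    long long bx = 0;
    for (int i = 0; i < N; ++i)
      if (bound[i] && (best < 0 || pos[i] > bx)) { best = i; bx = pos[i]; }
    return best;
  }

  void set_state(const IntegerVector &pos0, const LogicalVector &bound0) {
    for (int i = 0; i < N; ++i) {
      pos[i] = pos0[i];
      bound[i] = bound0[i] ? 1 : 0;
      if (bound[i]) { occ.insert(pos[i]); ++n_bound; }
    }
    refresh_window(true);
  }

  // Recompute the binding window from the current bound extremes; when no
  // motor is bound the window is kept from when motors were last attached.
  void refresh_window(bool force = false) {
    if (n_bound == 0 && !force) return;
    long long lo = 0, hi = 0;
    bool any = false;
    for (int i = 0; i < N; ++i)
      if (bound[i]) {
        if (!any) { lo = hi = pos[i]; any = true; }
        else { if (pos[i] < lo) lo = pos[i]; if (pos[i] > hi) hi = pos[i]; }
      }
    if (scenario == SCEN_A) {
      if (any) { wl = lo; wr = wl + M_fixed - 1; }
      else if (force) { wl = 0; wr = M_fixed - 1; }
    } else if (scenario == SCEN_B) {
      if (any) { wl = lo - 1; wr = hi + 1; }
      else if (force) { wl = -1; wr = 1; }
    }
  }

  // Scenario B sequence rule: the sites admissible to motor mu form the
  // open interval between its nearest bound lower- and higher-index
  // neighbours (all free: bound positions are ordered by index), with the
  // window edge +- 1 standing in for a missing neighbour (the one-extra-
  // site end extension). Returns the interval as [lo, hi]; empty if
  // hi < lo.
  void admissible_interval_B(int mu, long long &lo, long long &hi) const {
    long long lb = wl - 1, ub = wr + 1;
    for (int j = mu - 1; j >= 0; --j)
      if (bound[j]) { lb = pos[j]; break; }
    for (int j = mu + 1; j < N; ++j)
      if (bound[j]) { ub = pos[j]; break; }
    lo = lb + 1;
    hi = ub - 1;
  }

  // Free sites inside the scenario A window.
  void free_window_sites(std::vector<long long> &sites) const {
    sites.clear();
    for (long long s = wl; s <= wr; ++s)
      if (!occ.count((int)s)) sites.push_back(s);
  }

  void bind(int mu, long long s, double t) {
    pos[mu] = (int)s;
    bound[mu] = 1;
    occ.insert((int)s);
    ++n_bound;
    if (n_bound == 1) {
      run_active = true;
      run_measured = false;  // set by caller once past burn-in
      run_x0 = s;
    }
  }

  void unbind(int mu) {
    occ.erase(pos[mu]);
    bound[mu] = 0;
    --n_bound;
  }

  // Close the current leader episode at time t (position of the departing
  // leader is still stored in pos[]); record only episodes fully inside
  // the measurement window.
  void close_episode(double t) {
    if (ep_leader >= 0 && ep_measured && t > ep_t0) {
      episode_v.push_back((pos[ep_leader] - ep_x0) / (t - ep_t0));
      episode_w.push_back(t - ep_t0);
    }
    ep_leader = -1;
  }

  void update_leader(double t, bool measuring) {
    int cur = leader();
    if (cur != ep_leader) {
      close_episode(t);
      if (cur >= 0) {
        ep_leader = cur;
        ep_t0 = t;
        ep_x0 = pos[cur];
        ep_measured = measuring;
      }
    }
  }

  void finish_run(int last_mu, bool measuring) {
    if (run_active && run_measured && measuring)
      run_len.push_back((double)(pos[last_mu] - run_x0));
    run_active = false;
  }
};

// Fisher-Yates permutation using R's RNG.
inline void rand_perm(std::vector<int> &idx) {
  const int n = (int)idx.size();
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

}  // namespace

// Fixed time-step engine. Runs n_steps steps of size dt; observables are
// accumulated once step >= burn_in. Initial state is supplied from R
// (processive: motors placed and bound; non-processive: all unbound).
// [[Rcpp::export(name = ".run_fixed_cpp")]]
List run_fixed_cpp(int N, double p, double q, double delta, double kon,
                   double koff, double f, double dt, double n_steps,
                   double burn_in, int scenario, int M_fixed,
                   IntegerVector init_pos, LogicalVector init_bound,
                   bool record_states = false) {
  Engine e(N, p, q, delta, kon, koff, f, dt, scenario, M_fixed);
  e.set_state(init_pos, init_bound);

  const long long T = (long long)n_steps;
  const long long ts = (long long)burn_in;
  const bool nonproc = (scenario != PROCESSIVE);
  const double Pon = kon * dt, Poff = koff * dt;
  const double Pf = p * dt, Pb = q * dt;
  const double Pf1 = e.p1 * dt, Pb1 = e.q1 * dt;

  std::vector<int> order(N);
  std::vector<long long> scratch_sites;
  IntegerMatrix pos_hist;
  IntegerMatrix bound_hist;
  if (record_states) {
    pos_hist = IntegerMatrix((int)T, N);
    bound_hist = IntegerMatrix((int)T, N);
  }

  long long x_ref = 0;        // leader position at burn-in (processive)
  bool have_ref = false;

  e.update_leader(0.0, false);

  for (long long step = 0; step < T; ++step) {
    const bool measuring = step >= ts;

    // Phase 1: binding / unbinding in fresh random order.
    if (nonproc) {
      rand_perm(order);
      const double M = (double)e.window_size();
      for (int k = 0; k < N; ++k) {
        const int mu = order[k];
        const double u = unif_rand();
        if (e.bound[mu]) {
          if (u < Poff) {
            const bool last = (e.n_bound == 1);
            e.unbind(mu);
            if (last) e.finish_run(mu, measuring);
          }
        } else if (u < Pon) {
          long long s = 0;
          bool ok = false;
          if (scenario == SCEN_A) {
            // random reach over the M window sites: fail on occupied ones
            if (unif_rand() * M < M - (double)e.n_bound) {
              e.free_window_sites(scratch_sites);
              if (!scratch_sites.empty()) {
                s = scratch_sites[(size_t)(unif_rand() *
                                           scratch_sites.size()) %
                                  scratch_sites.size()];
                ok = true;
              }
            }
          } else {
            long long lo, hi;
            e.admissible_interval_B(mu, lo, hi);
            if (hi >= lo) {
              s = lo + (long long)(unif_rand() * (double)(hi - lo + 1));
              if (s > hi) s = hi;
              ok = true;
            }
          }
          if (ok) {
            e.bind(mu, s, step * dt);
            if (e.n_bound == 1) e.run_measured = measuring;
          }
        }
      }
    }

    // Leadership can only change through binding and unbinding (exclusion
    // forbids overtaking), so episodes open and close here, before the
    // stepping phase, with the leader's position not yet advanced this
    // step. The leader then stays fixed through the stepping phase.
    e.update_leader(step * dt, measuring);
    const int lead = e.ep_leader;

    // Phase 2: stepping of bound motors in fresh random order.
    rand_perm(order);
    for (int k = 0; k < N; ++k) {
      const int mu = order[k];
      if (!e.bound[mu]) continue;
      const double pf = (mu == lead) ? Pf1 : Pf;
      const double pb = (mu == lead) ? Pb1 : Pb;
      const double u = unif_rand();
      int dir = 0;
      if (u < pf) dir = 1;
      else if (u < pf + pb) dir = -1;
      if (dir != 0) {
        const int target = e.pos[mu] + dir;
        if (!e.occ.count(target)) {
          e.occ.erase(e.pos[mu]);
          e.pos[mu] = target;
          e.occ.insert(target);
        }
      }
    }

    // End of step: window follows the moved/bound extremes.
    e.refresh_window();

    if (measuring) {
      e.occ_w[e.n_bound] += 1.0;
      e.window_w += (double)e.window_size();
      e.meas_w += 1.0;
    }
    if (!have_ref && step + 1 >= ts) {
      const int l = e.leader();
      x_ref = (l >= 0) ? e.pos[l] : 0;
      have_ref = true;
    }
    if (record_states) {
      for (int i = 0; i < N; ++i) {
        pos_hist((int)step, i) = e.pos[i];
        bound_hist((int)step, i) = e.bound[i] ? 1 : 0;
      }
    }
  }

  // End-to-end steady-state velocity of the leading motor (meaningful for
  // processive runs, where the leader never detaches).
  double v_ss = NA_REAL;
  const int l_end = e.leader();
  if (!nonproc && have_ref && l_end >= 0 && T > ts)
    v_ss = (e.pos[l_end] - x_ref) / ((T - ts) * dt);

  NumericVector occw(e.occ_w.begin(), e.occ_w.end());
  List out = List::create(
      _["episode_velocities"] = NumericVector(e.episode_v.begin(),
                                              e.episode_v.end()),
      _["episode_durations"] = NumericVector(e.episode_w.begin(),
                                             e.episode_w.end()),
      _["run_lengths"] = NumericVector(e.run_len.begin(), e.run_len.end()),
      _["occupancy_weights"] = occw,
      _["mean_window"] = e.meas_w > 0 ? e.window_w / e.meas_w : NA_REAL,
      _["steady_state_velocity"] = v_ss,
      _["positions"] = IntegerVector(e.pos.begin(), e.pos.end()),
      _["bound"] = LogicalVector(e.bound.begin(), e.bound.end()),
      _["window"] = NumericVector::create((double)e.wl, (double)e.wr));
  if (record_states) {
    out["pos_hist"] = pos_hist;
    out["bound_hist"] = bound_hist;
  }
  return out;
}

// Event-driven (Gillespie) engine for the identical Markov process: exact
// exponential waiting times, events chosen proportionally to rate, same
// admissibility rules and observable definitions as the fixed-step engine.
// total_time is in seconds; burn_in_time likewise.
// [[Rcpp::export(name = ".run_gillespie_cpp")]]
List run_gillespie_cpp(int N, double p, double q, double delta, double kon,
                       double koff, double f, double total_time,
                       double burn_in_time, int scenario, int M_fixed,
                       IntegerVector init_pos, LogicalVector init_bound,
                       bool record_events = false, int max_events_rec = 20000) {
  Engine e(N, p, q, delta, kon, koff, f, 1.0, scenario, M_fixed);
  e.set_state(init_pos, init_bound);
  const bool nonproc = (scenario != PROCESSIVE);

  // 4 channels per motor: 0 fwd, 1 bwd, 2 unbind, 3 bind
  std::vector<double> rate(4 * N, 0.0);
  std::vector<double> ev_times;

  double t = 0.0;
  bool have_ref = false;
  e.update_leader(0.0, false);

  auto accumulate = [&](double t0, double t1) {
    // time-weighted occupancy/window accumulation over [t0, t1)
    const double a = std::max(t0, burn_in_time);
    if (t1 > a) {
      const double w = t1 - a;
      e.occ_w[e.n_bound] += w;
      e.window_w += w * (double)e.window_size();
      e.meas_w += w;
    }
  };

  long long x_ref_i = 0;
  while (t < total_time) {
    // Build the rate table (full rebuild per event; O(N)).
    const int lead = e.leader();
    const long long M = e.window_size();
    double total = 0.0;
    for (int mu = 0; mu < N; ++mu) {
      double *r = &rate[4 * mu];
      r[0] = r[1] = r[2] = r[3] = 0.0;
      if (e.bound[mu]) {
        const double pm = (mu == lead) ? e.p1 : p;
        const double qm = (mu == lead) ? e.q1 : q;
        if (!e.occ.count(e.pos[mu] + 1)) r[0] = pm;
        if (!e.occ.count(e.pos[mu] - 1)) r[1] = qm;
        if (nonproc) r[2] = koff;
      } else if (nonproc) {
        if (e.scenario == SCEN_A) {
          r[3] = kon * (double)(M - e.n_bound) / (double)M;
        } else {
          long long lo, hi;
          e.admissible_interval_B(mu, lo, hi);
          if (hi >= lo) r[3] = kon;
        }
      }
      total += r[0] + r[1] + r[2] + r[3];
    }

    if (total <= 0.0) {  // frozen state: advance to the horizon
      accumulate(t, total_time);
      t = total_time;
      break;
    }

    const double wait = -std::log(unif_rand()) / total;
    double t_next = t + wait;
    if (t_next > total_time) {
      accumulate(t, total_time);
      t = total_time;
      break;
    }
    accumulate(t, t_next);

    if (!have_ref && t_next >= burn_in_time) {
      const int l = e.leader();
      x_ref_i = (l >= 0) ? e.pos[l] : 0;
      have_ref = true;
    }
    if (record_events && (int)ev_times.size() < max_events_rec)
      ev_times.push_back(t_next);

    // Select the event proportionally to rate.
    double target = unif_rand() * total;
    int sel = -1;
    for (int i = 0; i < 4 * N; ++i) {
      if (rate[i] <= 0.0) continue;
      target -= rate[i];
      if (target <= 0.0) { sel = i; break; }
    }
    if (sel < 0)  // guard against rounding at the far end of the table
      for (int i = 4 * N - 1; i >= 0; --i)
        if (rate[i] > 0.0) { sel = i; break; }
    const int mu = sel / 4, ch = sel % 4;

    const bool measuring = t_next >= burn_in_time;
    if (ch == 0 || ch == 1) {
      const int dir = (ch == 0) ? 1 : -1;
      e.occ.erase(e.pos[mu]);
      e.pos[mu] += dir;
      e.occ.insert(e.pos[mu]);
    } else if (ch == 2) {
      const bool last = (e.n_bound == 1);
      e.unbind(mu);
      if (last) e.finish_run(mu, measuring);
    } else {
      // bind: the rate already carries the scenario's acceptance factor;
      // land uniformly on an eligible site
      bool ok = false;
      long long s = 0;
      if (e.scenario == SCEN_A) {
        std::vector<long long> sites;
        e.free_window_sites(sites);
        if (!sites.empty()) {
          s = sites[(size_t)(unif_rand() * sites.size()) % sites.size()];
          ok = true;
        }
      } else {
        long long lo, hi;
        e.admissible_interval_B(mu, lo, hi);
        if (hi >= lo) {
          s = lo + (long long)(unif_rand() * (double)(hi - lo + 1));
          if (s > hi) s = hi;
          ok = true;
        }
      }
      if (ok) {
        e.bind(mu, s, t_next);
        if (e.n_bound == 1) e.run_measured = measuring;
      }
    }

    e.refresh_window();
    e.update_leader(t_next, measuring);
    t = t_next;
  }

  double v_ss = NA_REAL;
  const int l_end = e.leader();
  if (!nonproc && have_ref && l_end >= 0 && total_time > burn_in_time)
    v_ss = (e.pos[l_end] - x_ref_i) / (total_time - burn_in_time);

  return List::create(
      _["episode_velocities"] = NumericVector(e.episode_v.begin(),
                                              e.episode_v.end()),
      _["episode_durations"] = NumericVector(e.episode_w.begin(),
                                             e.episode_w.end()),
      _["run_lengths"] = NumericVector(e.run_len.begin(), e.run_len.end()),
      _["occupancy_weights"] = NumericVector(e.occ_w.begin(), e.occ_w.end()),
      _["mean_window"] = e.meas_w > 0 ? e.window_w / e.meas_w : NA_REAL,
      _["steady_state_velocity"] = v_ss,
      _["positions"] = IntegerVector(e.pos.begin(), e.pos.end()),
      _["bound"] = LogicalVector(e.bound.begin(), e.bound.end()),
      _["window"] = NumericVector::create((double)e.wl, (double)e.wr),
      _["event_times"] = NumericVector(ev_times.begin(), ev_times.end()));
}
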
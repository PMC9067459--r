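#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Time-dependent rate schedule for one mRNA.
//
// Time origin: t = 0 is stress onset. t < 0 is pre-stress (log phase)
// burn-in. t >= t_readd (if finite) is the post-readdition phase with
// constant restored rates.
//
// alpha modes (initiation, events/s per mRNA):
//   0: constant alpha0
//   1: alpha0 * (floor + (1 - floor) * exp(-(t - t_stress)/alpha_tau))
//   2: alpha0 * alpha_factor
// k modes (elongation, codons/s):
//   0: constant k0
//   1: k0 / (1 + (t - t_stress)/k_tau)      (hyperbolic slowdown)
//   2: k0 * k_factor
// A positional slow zone (codons <= k_slow_codon_max get factor
// k_slow_factor) applies only for t >= t_stress (heat-shock style 5'
// pausing).
struct Sched {
  double t_stress, t_readd;
  double alpha0, alpha_tau, alpha_floor, alpha_factor, alpha_readd;
  double k0, k_tau, k_factor, k_readd;
  double k_slow_factor;
  int alpha_mode, k_mode, k_slow_codon_max;
};

static Sched sched_from_list(const List& s) {
  Sched sc;
  sc.t_stress        = as<double>(s["t_stress"]);
  sc.t_readd         = as<double>(s["t_readd"]);
  sc.alpha0          = as<double>(s["alpha0"]);
  sc.alpha_mode      = as<int>(s["alpha_mode"]);
  sc.alpha_tau       = as<double>(s["alpha_tau"]);
  sc.alpha_floor     = as<double>(s["alpha_floor"]);
  sc.alpha_factor    = as<double>(s["alpha_factor"]);
  sc.alpha_readd     = as<double>(s["alpha_readd"]);
  sc.k0              = as<double>(s["k0"]);
  sc.k_mode          = as<int>(s["k_mode"]);
  sc.k_tau           = as<double>(s["k_tau"]);
  sc.k_factor        = as<double>(s["k_factor"]);
  sc.k_readd         = as<double>(s["k_readd"]);
  sc.k_slow_codon_max = as<int>(s["k_slow_codon_max"]);
  sc.k_slow_factor   = as<double>(s["k_slow_factor"]);
  return sc;
}

static inline double alpha_at(const Sched& s, double t) {
  if (t < s.t_stress) return s.alpha0;
  if (t >= s.t_readd) return s.alpha_readd;
  switch (s.alpha_mode) {
  case 1:
    return s.alpha0 * (s.alpha_floor +
                       (1.0 - s.alpha_floor) * std::exp(-(t - s.t_stress) / s.alpha_tau));
  case 2:
    return s.alpha0 * s.alpha_factor;
  default:
    return s.alpha0;
  }
}

static inline double k_base_at(const Sched& s, double t) {
  if (t < s.t_stress) return s.k0;
  if (t >= s.t_readd) return s.k_readd;
  switch (s.k_mode) {
  case 1:
    return s.k0 / (1.0 + (t - s.t_stress) / s.k_tau);
  case 2:
    return s.k0 * s.k_factor;
  default:
    return s.k0;
  }
}

static inline double k_at(const Sched& s, double t, int codon) {
  double k = k_base_at(s, t);
  if (t >= s.t_stress && s.k_slow_codon_max > 0 && codon <= s.k_slow_codon_max)
    k *= s.k_slow_factor;
  return k;
}

// Exact event-driven simulation of one mRNA copy as a TASEP with extended
// particles (footprint ell codons). Time-dependent rates are handled by
// Poisson thinning against piecewise-constant upper bounds: within each
// phase (pre-stress / stress / post-readdition) alpha and base k are
// non-increasing in t, so the bound taken at the left edge of a short
// refresh window is valid throughout the window.
//
// Rules (positions are P-site codon indices, 1-based):
//  - initiation at rate alpha(t) succeeds iff codons 1..ell are free
//    (leading ribosome at position > ell);
//  - ribosome at codon j < L hops to j+1 at rate k(t, j) iff the ribosome
//    ahead (if any) is at position > j + ell;
//  - ribosome at codon L terminates at rate beta and leaves.
//
// [[Rcpp::export]]
List sim_tasep_cpp(int L, int ell, double beta, List schedule,
                   double t_start, double t_end,
                   NumericVector snapshot_times,
                   IntegerVector init_positions,
                   double bound_refresh = 5.0,
                   double max_events = 5e7) {
  if (L < 1) stop("L must be >= 1");
  if (ell < 1) stop("ell must be >= 1");
  Sched sc = sched_from_list(schedule);

  std::vector<int> pos;          // ascending codon order (5' -> 3')
  std::vector<double> itime;     // initiation time per ribosome (t_start for preloaded)
  for (int i = 0; i < init_positions.size(); ++i) {
    pos.push_back(init_positions[i]);
    itime.push_back(t_start);
  }
  for (size_t i = 1; i < pos.size(); ++i)
    if (pos[i] - pos[i - 1] < ell) stop("init_positions violate exclusion headway");
  if (!pos.empty() && (pos.front() < 1 || pos.back() > L))
    stop("init_positions outside 1..L");

  int n_snap = snapshot_times.size();
  List snap_pos(n_snap), snap_itime(n_snap);
  int next_snap = 0;

  std::vector<double> term_times;
  int n_init = 0, n_term = 0;
  double ev = 0.0;

  double t = t_start;
  RNGScope rng;

  while (t < t_end) {
    // window over which the thinning bounds hold
    double w_end = std::min(t + bound_refresh, t_end);
    if (t < sc.t_stress) w_end = std::min(w_end, sc.t_stress);
    if (t < sc.t_readd)  w_end = std::min(w_end, sc.t_readd);
    double alpha_up = alpha_at(sc, t);
    double k_up = k_base_at(sc, t);

    while (t < w_end) {
      int n = (int)pos.size();
      bool at_end = (n > 0 && pos[n - 1] == L);
      double R_up = alpha_up + (at_end ? beta : 0.0) + k_up * (n - (at_end ? 1 : 0));
      if (R_up <= 0.0) { t = w_end; break; }
      double dt = -std::log(unif_rand()) / R_up;
      double t_new = t + dt;
      // record any snapshots passed (state unchanged on (t, t_new))
      while (next_snap < n_snap && snapshot_times[next_snap] <= t_new &&
             snapshot_times[next_snap] <= t_end) {
        snap_pos[next_snap] = IntegerVector(pos.begin(), pos.end());
        snap_itime[next_snap] = NumericVector(itime.begin(), itime.end());
        ++next_snap;
      }
      if (t_new >= w_end) { t = w_end; break; }
      t = t_new;
      if (++ev > max_events)
        stop("event cap exceeded (%.0f events); check rates/duration", max_events);

      double u = unif_rand() * R_up;
      if (u < alpha_up) {
        // initiation attempt (thinning acceptance, then exclusion)
        if (unif_rand() * alpha_up <= alpha_at(sc, t) &&
            (n == 0 || pos[0] > ell) && L >= 1) {
          pos.insert(pos.begin(), 1);
          itime.insert(itime.begin(), t);
          ++n_init;
        }
        continue;
      }
      u -= alpha_up;
      if (at_end && u < beta) {
        // termination of the 3'-most ribosome (constant rate: always accept)
        term_times.push_back(t);
        pos.pop_back();
        itime.pop_back();
        ++n_term;
        continue;
      }
      if (at_end) u -= beta;
      int i = (int)(u / k_up);
      int n_mov = n - (at_end ? 1 : 0);
      if (i >= n_mov) i = n_mov - 1;  // guard FP edge
      if (i < 0) continue;
      int j = pos[i];
      if (j >= L) continue;  // only the terminator sits at L
      bool blocked = (i < n - 1 && pos[i + 1] - j <= ell);
      if (!blocked && unif_rand() * k_up <= k_at(sc, t, j)) pos[i] = j + 1;
    }
  }

  // snapshots at or after final time
  while (next_snap < n_snap) {
    snap_pos[next_snap] = IntegerVector(pos.begin(), pos.end());
    snap_itime[next_snap] = NumericVector(itime.begin(), itime.end());
    ++next_snap;
  }

  return List::create(
    _["positions"] = snap_pos,
    _["init_times"] = snap_itime,
    _["n_init"] = n_init,
    _["n_term"] = n_term,
    _["term_times"] = NumericVector(term_times.begin(), term_times.end()),
    _["final_positions"] = IntegerVector(pos.begin(), pos.end())
  );
}
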
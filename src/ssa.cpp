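// Delayed stochastic simulation algorithm: Gillespie direct method with a
// binary-heap wait list for delayed product release and per-species reaction
// dependency lists so that only affected propensities are recomputed after
// each event. Uses R's RNG (RNGScope) so set.seed() in R fixes trajectories
// bit-identically.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Release {
  double time;
  long long seq;   // insertion order breaks exact-time ties deterministically
  int species;
  int count;
};
struct ReleaseLater {
  bool operator()(const Release& a, const Release& b) const {
    if (a.time != b.time) return a.time > b.time;
    return a.seq > b.seq;
  }
};

inline double draw_delay(int kind, double p1, double p2) {
  switch (kind) {
  case 0: return 0.0;                       // none
  case 1: return p1;                        // constant
  case 2: {                                 // gaussian, truncated at 0
    for (int i = 0; i < 100; ++i) {
      double d = ::Rf_rnorm(p1, p2);
      if (d >= 0.0) return d;
    }
    return 0.0;
  }
  case 3: return ::Rf_rgamma(p1, p2);       // gamma(shape, scale)
  case 4: return ::exp_rand() / p1;         // exponential(rate)
  default: stop("unknown delay kind code");
  }
  return 0.0;
}

inline double nchoosek(double n, int k) {
  // falling-factorial / k! combinatorial propensity factor
  if (n < k) return 0.0;
  double v = 1.0;
  for (int i = 0; i < k; ++i) v *= (n - i) / (i + 1);
  return v;
}

} // namespace

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(IntegerVector init,
                 NumericVector rate,
                 IntegerVector re_off, IntegerVector re_sp,
                 IntegerVector re_st, LogicalVector re_cons,
                 IntegerVector pr_off, IntegerVector pr_sp,
                 IntegerVector pr_st, IntegerVector pr_dk,
                 NumericVector pr_p1, NumericVector pr_p2,
                 IntegerVector wl_sp, IntegerVector wl_ct,
                 NumericVector wl_t,
                 NumericVector grid,
                 bool log_events, int max_events) {
  const int ns = init.size();
  const int nr = rate.size();
  const int ng = grid.size();
  const double t_end = grid[ng - 1];

  std::vector<double> x(ns);
  for (int i = 0; i < ns; ++i) x[i] = init[i];

  // dependency lists: reactions whose propensity reads species s
  std::vector<std::vector<int>> dep(ns);
  for (int j = 0; j < nr; ++j)
    for (int k = re_off[j]; k < re_off[j + 1]; ++k)
      dep[re_sp[k]].push_back(j);

  std::vector<double> a(nr);
  double atot = 0.0;
  auto prop = [&](int j) {
    double v = rate[j];
    for (int k = re_off[j]; k < re_off[j + 1] && v > 0.0; ++k)
      v *= nchoosek(x[re_sp[k]], re_st[k]);
    return v;
  };
  for (int j = 0; j < nr; ++j) { a[j] = prop(j); atot += a[j]; }

  std::priority_queue<Release, std::vector<Release>, ReleaseLater> heap;
  long long seq = 0;
  for (int i = 0; i < wl_sp.size(); ++i)
    heap.push({wl_t[i], seq++, wl_sp[i], wl_ct[i]});

  IntegerMatrix snap(ns, ng);
  int gi = 0;
  double t = grid[0];

  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_id; // kind 0 = reaction firing, 1 = release

  RNGScope rng;
  bool deadlock = false;
  long long n_events = 0, refresh = 0;
  const double inf = std::numeric_limits<double>::infinity();

  auto take_snapshots = [&](double upto) {
    while (gi < ng && grid[gi] < upto) {
      if (grid[gi] > t_end) break;
      for (int s = 0; s < ns; ++s) snap(s, gi) = (int) x[s];
      ++gi;
    }
  };
  auto changed = [&](int s, double delta) {
    x[s] += delta;
    for (int j : dep[s]) { atot -= a[j]; a[j] = prop(j); atot += a[j]; }
  };

  for (;;) {
    if (++refresh % 16384 == 0 || atot < 0.0) {
      atot = 0.0;
      for (int j = 0; j < nr; ++j) { a[j] = prop(j); atot += a[j]; }
    }
    double t_fire = (atot > 0.0) ? t + ::exp_rand() / atot : inf;
    double t_rel = heap.empty() ? inf : heap.top().time;
    double t_next = (t_rel <= t_fire) ? t_rel : t_fire;

    if (t_next > t_end || t_next == inf) {
      // deadlock or horizon reached: fast-forward to the end of the grid
      if (t_next == inf) deadlock = true;
      take_snapshots(t_end + 1.0);
      break;
    }
    // a snapshot at grid time g reflects every event with time <= g, so
    // flush grid points strictly before the next event first
    take_snapshots(t_next);

    if (t_rel <= t_fire) {        // tie-break: releases are already committed
      Release r = heap.top(); heap.pop();
      t = r.time;
      changed(r.species, r.count);
      if (log_events) { ev_t.push_back(t); ev_kind.push_back(1);
                        ev_id.push_back(r.species); }
    } else {
      t = t_fire;
      double u = ::unif_rand() * atot;
      int j = nr - 1;
      double cum = 0.0;
      for (int k = 0; k < nr; ++k) {
        cum += a[k];
        if (u <= cum) { j = k; break; }
      }
      for (int k = re_off[j]; k < re_off[j + 1]; ++k)
        if (re_cons[k]) changed(re_sp[k], -re_st[k]);
      for (int k = pr_off[j]; k < pr_off[j + 1]; ++k) {
        if (pr_dk[k] == 0) {
          changed(pr_sp[k], pr_st[k]);
        } else {
          double tau = draw_delay(pr_dk[k], pr_p1[k], pr_p2[k]);
          heap.push({t + tau, seq++, pr_sp[k], pr_st[k]});
        }
      }
      if (log_events) { ev_t.push_back(t); ev_kind.push_back(0);
                        ev_id.push_back(j); }
    }
    if (++n_events >= (long long) max_events)
      stop("event budget exceeded (%d events before t = %g); "
           "raise max_events or shorten the run", max_events, t);
  }

  List out = List::create(_["snapshots"] = snap,
                          _["n_events"] = (double) n_events,
                          _["deadlock"] = deadlock);
  if (log_events) {
    out["event_time"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_kind"] = IntegerVector(ev_kind.begin(), ev_kind.end());
    out["event_id"] = IntegerVector(ev_id.begin(), ev_id.end());
  }
  return out;
}
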
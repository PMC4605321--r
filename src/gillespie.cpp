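// Continuous-time, discrete-state (Gillespie) simulation of the R-loop
// length m on 0..N. vf[i] (0-based) is the rate of the transition i -> i+1
// for i = 0..N-1; vr[i] is the rate of i+1 -> i. All draws come from R's RNG
// so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Chain {
  const double* vf;
  const double* vr;
  int N;
  bool absorbing;

  inline double up(int m) const { return (m < N) ? vf[m] : 0.0; }
  inline double down(int m) const { return (m > 0) ? vr[m - 1] : 0.0; }
};

}  // namespace

// Full event path. Returns times (event times, starting at 0), states
// (state entered at each time, starting at m0), absorbed flag and time.
// [[Rcpp::export(name = ".kmc_path_cpp")]]
List kmc_path_cpp(NumericVector vf, NumericVector vr, int m0, double max_t,
                  bool absorbing) {
  Chain ch{vf.begin(), vr.begin(), (int)vf.size(), absorbing};
  if (m0 < 0 || m0 > ch.N) stop("invalid initial state m0 = %d", m0);
  std::vector<double> times;
  std::vector<int> states;
  times.push_back(0.0);
  states.push_back(m0);
  double t = 0.0;
  int m = m0;
  bool absorbed = false;
  double t_abs = NA_REAL;
  while (true) {
    if (absorbing && m == 0) { absorbed = true; t_abs = t; break; }
    double a_up = ch.up(m), a_down = ch.down(m);
    double total = a_up + a_down;
    if (total <= 0.0) break;  // legally frozen until max_t
    t += R::exp_rand() / total;
    if (t >= max_t) break;
    m += (unif_rand() * total < a_up) ? 1 : -1;
    times.push_back(t);
    states.push_back(m);
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["absorbed"] = absorbed, _["t_abs"] = t_abs);
}

// Time spent in each state over [0, max_t]; length N+1 vector indexed by m.
// Time after absorption accrues to state 0.
// [[Rcpp::export(name = ".kmc_time_per_state_cpp")]]
NumericVector kmc_time_per_state_cpp(NumericVector vf, NumericVector vr,
                                     int m0, double max_t, bool absorbing) {
  Chain ch{vf.begin(), vr.begin(), (int)vf.size(), absorbing};
  if (m0 < 0 || m0 > ch.N) stop("invalid initial state m0 = %d", m0);
  NumericVector occ(ch.N + 1);
  double t = 0.0;
  int m = m0;
  while (t < max_t) {
    if (ch.absorbing && m == 0) { occ[0] += max_t - t; break; }
    double a_up = ch.up(m), a_down = ch.down(m);
    double total = a_up + a_down;
    if (total <= 0.0) { occ[m] += max_t - t; break; }
    double dt = R::exp_rand() / total;
    double t_next = t + dt;
    occ[m] += std::min(t_next, max_t) - t;
    t = t_next;
    if (t >= max_t) break;
    m += (unif_rand() * total < a_up) ? 1 : -1;
  }
  return occ;
}

// Replicated threshold occupancy: per-replicate fraction of [0, max_t] with
// m >= m_star (absorbed remainder counts as m = 0).
// [[Rcpp::export(name = ".kmc_threshold_reps_cpp")]]
NumericVector kmc_threshold_reps_cpp(NumericVector vf, NumericVector vr,
                                     int m0, double max_t, int m_star,
                                     bool absorbing, int reps) {
  Chain ch{vf.begin(), vr.begin(), (int)vf.size(), absorbing};
  if (m0 < 0 || m0 > ch.N) stop("invalid initial state m0 = %d", m0);
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double t = 0.0, above = 0.0;
    int m = m0;
    while (t < max_t) {
      if (ch.absorbing && m == 0) break;
      double a_up = ch.up(m), a_down = ch.down(m);
      double total = a_up + a_down;
      if (total <= 0.0) { if (m >= m_star) above += max_t - t; break; }
      double dt = R::exp_rand() / total;
      double t_next = std::min(t + dt, max_t);
      if (m >= m_star) above += t_next - t;
      t += dt;
      if (t >= max_t) break;
      m += (unif_rand() * total < a_up) ? 1 : -1;
    }
    out[r] = above / max_t;
  }
  return out;
}

// Replicated first-passage time from m0 to the first state < m_star.
// NA when censored at max_t (or absorbed-at-zero cannot happen: hitting 0
// is itself below m_star for m_star >= 1).
// [[Rcpp::export(name = ".kmc_first_passage_reps_cpp")]]
NumericVector kmc_first_passage_reps_cpp(NumericVector vf, NumericVector vr,
                                         int m0, int m_star, double max_t,
                                         bool absorbing, int reps) {
  Chain ch{vf.begin(), vr.begin(), (int)vf.size(), absorbing};
  if (m0 < 0 || m0 > ch.N) stop("invalid initial state m0 = %d", m0);
  if (m0 < m_star) stop("start state m0 = %d already below m_star = %d", m0, m_star);
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double t = 0.0;
    int m = m0;
    double fp = NA_REAL;
    while (t < max_t) {
      double a_up = ch.up(m), a_down = ch.down(m);
      double total = a_up + a_down;
      if (total <= 0.0) break;
      t += R::exp_rand() / total;
      if (t >= max_t) break;
      m += (unif_rand() * total < a_up) ? 1 : -1;
      if (m < m_star) { fp = t; break; }
    }
    out[r] = fp;
  }
  return out;
}

// Replicated race between absorption at 0 and a stop state (reaching
// m >= stop_state). 1 = absorbed first, 0 = stop event first, NA = censored.
// [[Rcpp::export(name = ".kmc_falloff_reps_cpp")]]
IntegerVector kmc_falloff_reps_cpp(NumericVector vf, NumericVector vr,
                                   int m0, int stop_state, double max_t,
                                   int reps) {
  Chain ch{vf.begin(), vr.begin(), (int)vf.size(), true};
  if (m0 < 0 || m0 > ch.N) stop("invalid initial state m0 = %d", m0);
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double t = 0.0;
    int m = m0;
    int res = NA_INTEGER;
    if (m >= stop_state) res = 0;
    if (m == 0) res = 1;
    while (res == NA_INTEGER && t < max_t) {
      double a_up = ch.up(m), a_down = ch.down(m);
      double total = a_up + a_down;
      if (total <= 0.0) break;
      t += R::exp_rand() / total;
      if (t >= max_t) break;
      m += (unif_rand() * total < a_up) ? 1 : -1;
      if (m == 0) res = 1;
      else if (m >= stop_state) res = 0;
    }
    out[r] = res;
  }
  return out;
}
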
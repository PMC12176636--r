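// Event detection for the two-process model with the built-in cosine
// circadian waveform.  Pressure follows exact exponential closed forms
// within each vigilance state; switching times are located by bracketing
// the pressure-minus-active-threshold residual on a uniform grid (default
// step T_f/2048) and refining by bisection.  No numerical ODE integration.
//
// A pure-R mirror of next_crossing() lives in R/simulate.R (generic
// waveforms); the two implementations are cross-checked in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double chi_w, chi_s, mu_w, mu_s, H0p, H0m, a, Tf;
};

Pars as_pars(const List& p) {
  Pars q;
  q.chi_w = p["chi_w"]; q.chi_s = p["chi_s"];
  q.mu_w  = p["mu_w"];  q.mu_s  = p["mu_s"];
  q.H0p   = p["H0_plus"]; q.H0m = p["H0_minus"];
  q.a     = p["a"];     q.Tf    = p["T_f"];
  return q;
}

inline double thr(double t, double base, const Pars& p) {
  return base + p.a * std::cos(2.0 * M_PI * t / p.Tf);
}

inline double pressure(double t, double t0, double H0, bool wake, const Pars& p) {
  if (wake) return p.mu_w + (H0 - p.mu_w) * std::exp(-(t - t0) / p.chi_w);
  return p.mu_s + (H0 - p.mu_s) * std::exp(-(t - t0) / p.chi_s);
}

// residual has crossed the active threshold?
inline bool crossed(double g, bool wake) { return wake ? (g >= 0.0) : (g <= 0.0); }

// First time t* > t0 at which the pressure meets the active threshold.
// Returns NaN when no crossing can ever occur (asymptote outside the
// threshold band: perpetual wake/sleep) and +Inf when none occurs before
// t0 + tmax (or a tangency is missed at grid resolution).
// `immediate` is set when the state starts on the crossing side (possible
// at high amplitude straight after a switch): the caller re-switches after
// the minimum dwell.
double next_crossing(double t0, double H0, bool wake, const Pars& p,
                     double step, double tol, double dwell, double tmax,
                     bool* immediate) {
  *immediate = false;
  const double base = wake ? p.H0p : p.H0m;

  if (p.a == 0.0) {  // closed-form crossing, exact
    if (wake) {
      if (H0 >= base) { *immediate = true; return t0 + dwell; }
      if (p.mu_w <= base) return R_NaN;
      double dt = p.chi_w * std::log((p.mu_w - H0) / (p.mu_w - base));
      return (dt <= tmax) ? t0 + dt : R_PosInf;
    } else {
      if (H0 <= base) { *immediate = true; return t0 + dwell; }
      if (p.mu_s >= base) return R_NaN;
      double dt = p.chi_s * std::log((H0 - p.mu_s) / (base - p.mu_s));
      return (dt <= tmax) ? t0 + dt : R_PosInf;
    }
  }

  const double thrMin = base - p.a, thrMax = base + p.a;
  double g0 = pressure(t0 + dwell, t0, H0, wake, p) - thr(t0 + dwell, base, p);
  if (crossed(g0, wake)) { *immediate = true; return t0 + dwell; }

  // dt_lo: the crossing cannot occur before the pressure reaches the
  // nearest extreme of the oscillating threshold; dt_hi: it must occur by
  // the time the pressure passes the far extreme (or, when the asymptote
  // lies inside the threshold band, within one forcing period of the
  // pressure settling above/below the band midline).
  double lo = dwell, hi;
  if (wake) {
    if (p.mu_w <= thrMin) return R_NaN;  // perpetual wake
    if (H0 < thrMin)
      lo = std::max(dwell, p.chi_w * std::log((p.mu_w - H0) / (p.mu_w - thrMin)));
    if (p.mu_w > thrMax)
      hi = p.chi_w * std::log((p.mu_w - H0) / (p.mu_w - thrMax));
    else {
      double L = 0.5 * (p.mu_w + thrMin);
      hi = p.chi_w * std::log((p.mu_w - H0) / (p.mu_w - L)) + p.Tf;
    }
  } else {
    if (p.mu_s >= thrMax) return R_NaN;  // perpetual sleep
    if (H0 > thrMax)
      lo = std::max(dwell, p.chi_s * std::log((H0 - p.mu_s) / (thrMax - p.mu_s)));
    if (p.mu_s < thrMin)
      hi = p.chi_s * std::log((H0 - p.mu_s) / (thrMin - p.mu_s));
    else {
      double L = 0.5 * (p.mu_s + thrMax);
      hi = p.chi_s * std::log((H0 - p.mu_s) / (L - p.mu_s)) + p.Tf;
    }
  }
  hi = std::min(hi + step, tmax);
  if (lo >= hi) return R_PosInf;  // crossing (if any) lies beyond tmax

  double ta = t0 + lo;
  double ga = pressure(ta, t0, H0, wake, p) - thr(ta, base, p);
  double tb = ta;
  if (!crossed(ga, wake)) {
    bool found = false;
    for (double t = ta + step; t <= t0 + hi + step; t += step) {
      double tt = std::min(t, t0 + hi);
      double g = pressure(tt, t0, H0, wake, p) - thr(tt, base, p);
      if (crossed(g, wake)) { tb = tt; found = true; break; }
      ta = tt; ga = g;
      if (tt >= t0 + hi) break;
    }
    if (!found) return R_PosInf;  // tangency below grid resolution, or tmax cut
  } else {
    // crossed already at the analytic lower bound (tangency at the
    // threshold extreme); bracket back to the dwell point
    tb = ta; ta = t0 + dwell;
  }

  while (tb - ta > tol) {
    double tm = 0.5 * (ta + tb);
    double gm = pressure(tm, t0, H0, wake, p) - thr(tm, base, p);
    if (crossed(gm, wake)) tb = tm; else ta = tm;
  }
  return 0.5 * (ta + tb);
}

}  // namespace

// Simulate switch events from (t0, H0, state) until `horizon` hours.
// Returns the switch log: times, pressures at the switches, and the state
// that *ends* at each switch (1 = wake, 0 = sleep), plus a status string.
// [[Rcpp::export]]
List cpp_simulate_switches(List pars, double t0, double H0, bool wake0,
                           double horizon, double step, double tol,
                           double dwell) {
  Pars p = as_pars(pars);
  std::vector<double> times, press;
  std::vector<int> ended_state;
  double t = t0, H = H0;
  bool wake = wake0, immediate = false;
  std::string status = "OK";
  for (int iter = 0; iter < 2000000; ++iter) {
    // allow the search to run one period past the horizon; a +Inf return
    // then simply means no further event before the horizon
    double tc = next_crossing(t, H, wake, p, step, tol, dwell,
                              horizon - t + p.Tf, &immediate);
    if (ISNAN(tc)) { status = "NONTERMINATING"; break; }
    if (!R_finite(tc) || tc > horizon) break;
    double Hc = immediate ? H : pressure(tc, t, H, wake, p);
    times.push_back(tc);
    press.push_back(Hc);
    ended_state.push_back(wake ? 1 : 0);
    t = tc; H = Hc; wake = !wake;
  }
  return List::create(_["t"] = times, _["H"] = press,
                      _["ended_wake"] = ended_state, _["status"] = status);
}

// One crossing from a given state; thin wrapper used by find_next_switch().
// [[Rcpp::export]]
List cpp_next_crossing(List pars, double t0, double H0, bool wake,
                       double t_max, double step, double tol, double dwell) {
  Pars p = as_pars(pars);
  bool immediate = false;
  double tc = next_crossing(t0, H0, wake, p, step, tol, dwell, t_max - t0,
                            &immediate);
  return List::create(_["t"] = tc, _["immediate"] = immediate);
}

// Iterate the first-return (circle) map: starting from an upper-threshold
// hit at time phase0 * T_f, alternate one sleep and one wake segment
// n_steps times.  Returns the successive upper-threshold hit times (the
// lift, in hours).
// [[Rcpp::export]]
List cpp_circle_lift(List pars, double phase0, int n_steps, double step,
                     double tol, double dwell) {
  Pars p = as_pars(pars);
  NumericVector hits(n_steps);
  double t = phase0 * p.Tf;
  double H = thr(t, p.H0p, p);
  std::string status = "OK";
  bool immediate = false;
  int done = 0;
  // generous per-segment horizon: segments are bounded by the analytic
  // windows inside next_crossing; tmax only guards the pathological cases
  const double seg_max = 1e4 * p.Tf;
  for (int k = 0; k < n_steps; ++k) {
    double t1 = next_crossing(t, H, false, p, step, tol, dwell, seg_max,
                              &immediate);  // sleep -> lower threshold
    if (!R_finite(t1)) { status = ISNAN(t1) ? "NONTERMINATING" : "UNRESOLVED"; break; }
    double H1 = immediate ? H : pressure(t1, t, H, false, p);
    double t2 = next_crossing(t1, H1, true, p, step, tol, dwell, seg_max,
                              &immediate);  // wake -> upper threshold
    if (!R_finite(t2)) { status = ISNAN(t2) ? "NONTERMINATING" : "UNRESOLVED"; break; }
    H = immediate ? H1 : pressure(t2, t1, H1, true, p);
    t = t2;
    hits[k] = t2;
    done = k + 1;
  }
  return List::create(_["hits"] = hits, _["n_done"] = done,
                      _["status"] = status);
}
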
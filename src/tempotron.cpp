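#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Evaluate one afferent spike pattern on the tempotron.
//
// The soma potential V(t) = sum_i w_i sum_f K(t - t_i^f) with the
// double-exponential kernel K(dt) = V0 (exp(-dt/tau) - exp(-dt/tau_r)) is
// integrated on a regular grid by tracking the two exponential accumulators.
// A readout spike occurs at the first upward crossing of `v_thresh`; the
// shunt after the spike only suppresses later PSPs, so the first crossing
// (and hence the fired/not-fired outcome) is that of the un-shunted trace.
//
// Returns the first crossing (or -1), the time of the un-shunted voltage
// maximum t_max (ties -> earliest; an identically non-positive trace yields
// t_max = t_end so that a flat zero-weight tempotron still assigns credit to
// every afferent spike), and the per-afferent credit sum_{t_f < t_max}
// K(t_max - t_f) used by the learning rule.
//
// `aff` is 1-based; spikes must be sorted by time.
// [[Rcpp::export]]
List tempotron_eval(IntegerVector aff, NumericVector times, NumericVector w,
                    double tau, double tau_r, double V0, double v_thresh,
                    double t_end, double dt) {
  const int n_spk = aff.size();
  const int n_aff = w.size();
  double A = 0.0, B = 0.0;          // slow / fast exponential accumulators
  const double decA = std::exp(-dt / tau), decB = std::exp(-dt / tau_r);
  int ptr = 0;
  double vmax = 0.0, t_max = -1.0, t_spike = -1.0, vprev = 0.0;
  const int n_steps = (int)std::lround(t_end / dt);
  for (int s = 1; s <= n_steps; ++s) {
    const double t = s * dt;
    // decay over (t - dt, t], then add arrivals in that interval at t
    A *= decA;
    B *= decB;
    while (ptr < n_spk && times[ptr] <= t) {
      const double wi = w[aff[ptr] - 1];
      const double lag = t - times[ptr];   // sub-step alignment
      A += wi * std::exp(-lag / tau);
      B += wi * std::exp(-lag / tau_r);
      ++ptr;
    }
    const double V = V0 * (A - B);
    if (V > vmax) { vmax = V; t_max = t; }
    if (t_spike < 0 && vprev < v_thresh && V >= v_thresh) t_spike = t;
    vprev = V;
  }
  if (vmax <= 0.0) {
    // flat (e.g. all-zero-weight) trace: take the limit of vanishing equal
    // weights, i.e. the maximum of the unit-weight trace, so that a lone
    // afferent gets full credit at its PSP peak
    A = B = 0.0;
    ptr = 0;
    double umax = 0.0;
    t_max = t_end;
    for (int s = 1; s <= n_steps; ++s) {
      const double t = s * dt;
      A *= decA;
      B *= decB;
      while (ptr < n_spk && times[ptr] <= t) {
        const double lag = t - times[ptr];
        A += std::exp(-lag / tau);
        B += std::exp(-lag / tau_r);
        ++ptr;
      }
      const double V = V0 * (A - B);
      if (V > umax) { umax = V; t_max = t; }
    }
  }
  NumericVector dw(n_aff);
  for (int k = 0; k < n_spk; ++k) {
    if (times[k] < t_max) {
      const double lag = t_max - times[k];
      dw[aff[k] - 1] += V0 * (std::exp(-lag / tau) - std::exp(-lag / tau_r));
    }
  }
  return List::create(_["fired"] = t_spike >= 0, _["t_spike"] = t_spike,
                      _["t_max"] = t_max, _["v_max"] = vmax, _["dw"] = dw);
}
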
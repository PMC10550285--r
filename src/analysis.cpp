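#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cross-correlogram counts: histogram of lags (b - a) over all spike pairs,
// bins of width `bin` covering [-half_window, half_window).
// [[Rcpp::export]]
IntegerVector ccg_counts(NumericVector a, NumericVector b, double bin,
                         double half_window) {
  const int nbin = (int)std::lround(2.0 * half_window / bin);
  IntegerVector counts(nbin);
  for (int i = 0; i < a.size(); ++i) {
    for (int j = 0; j < b.size(); ++j) {
      const double lag = b[j] - a[i];
      if (lag >= -half_window && lag < half_window) {
        int k = (int)std::floor((lag + half_window) / bin);
        if (k >= nbin) k = nbin - 1;      // guard float round-up at the edge
        counts[k]++;
      }
    }
  }
  return counts;
}

// Mean resultant length of (phase - a * x) over a grid of slopes.
// [[Rcpp::export]]
NumericVector resultant_grid(NumericVector phase, NumericVector x,
                             NumericVector slopes) {
  const int n = phase.size(), m = slopes.size();
  NumericVector R(m);
  for (int k = 0; k < m; ++k) {
    double cs = 0.0, sn = 0.0;
    const double a = slopes[k];
    for (int j = 0; j < n; ++j) {
      const double th = phase[j] - a * x[j];
      cs += std::cos(th);
      sn += std::sin(th);
    }
    R[k] = std::sqrt(cs * cs + sn * sn) / n;
  }
  return R;
}
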
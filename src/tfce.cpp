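#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Threshold-free cluster enhancement of a 1-D nonnegative series.
// Discrete sum over n_steps height levels h_k = h0 + k*dh, k = 1..n_steps,
// dh = (max - h0)/n_steps, h0 = min(d).  For each level the supra-threshold
// mask (d >= h_k) is run-length encoded; every sample inside a run of
// duration e (in `unit`s, unit = dt for seconds or 1 for samples) gains
// e^E * h_k^H * dh.  Cost O(n_steps * length).  A constant series yields
// all zeros (zero-width integration range).
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector d, double E, double H,
                       int n_steps, double unit) {
  int n = d.size();
  NumericVector out(n);
  if (n == 0) return out;
  double h0 = d[0], hm = d[0];
  for (int i = 1; i < n; ++i) {
    if (d[i] < h0) h0 = d[i];
    if (d[i] > hm) hm = d[i];
  }
  if (hm <= h0) return out;
  double dh = (hm - h0) / n_steps;
  for (int k = 1; k <= n_steps; ++k) {
    double h = h0 + k * dh;
    int i = 0;
    while (i < n) {
      if (d[i] >= h) {
        int j = i;
        while (j < n && d[j] >= h) ++j;
        double e = (j - i) * unit;
        double term = std::pow(e, E) * std::pow(h, H) * dh;
        for (int t = i; t < j; ++t) out[t] += term;
        i = j;
      } else {
        ++i;
      }
    }
  }
  return out;
}
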
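#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Running minimum / maximum of y over a sliding window in x-units
// (|x_j - x_i| <= half_width), for a sorted, possibly non-uniform axis.
// Monotonic-deque algorithm, O(n). Windows shrink at the edges.
static NumericVector run_extremum(const NumericVector& x,
                                  const NumericVector& y,
                                  double half_width,
                                  bool want_min) {
  const int n = x.size();
  NumericVector out(n);
  std::deque<int> dq;
  int lo = 0, hi = -1;
  for (int i = 0; i < n; ++i) {
    while (hi + 1 < n && x[hi + 1] <= x[i] + half_width) {
      ++hi;
      double v = y[hi];
      if (want_min) {
        while (!dq.empty() && y[dq.back()] >= v) dq.pop_back();
      } else {
        while (!dq.empty() && y[dq.back()] <= v) dq.pop_back();
      }
      dq.push_back(hi);
    }
    while (lo < n && x[lo] < x[i] - half_width) {
      if (!dq.empty() && dq.front() == lo) dq.pop_front();
      ++lo;
    }
    out[i] = y[dq.front()];
  }
  return out;
}

// [[Rcpp::export(name = ".run_min")]]
NumericVector run_min(NumericVector x, NumericVector y, double half_width) {
  return run_extremum(x, y, half_width, true);
}

// [[Rcpp::export(name = ".run_max")]]
NumericVector run_max(NumericVector x, NumericVector y, double half_width) {
  return run_extremum(x, y, half_width, false);
}
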
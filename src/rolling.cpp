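#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Centered rolling minimum / maximum with an O(n) monotonic deque.
// Windows shrink at the edges to the available points.

static NumericVector roll_extreme(const NumericVector& x, int w, bool want_min) {
  const int n = x.size();
  if (w < 1) stop("window must be >= 1 points");
  const int half = w / 2;
  NumericVector out(n);
  std::deque<int> dq;  // indices, values monotone
  int right = -1;
  for (int i = 0; i < n; ++i) {
    const int hi = std::min(n - 1, i + half);
    const int lo = std::max(0, i - half);
    while (right < hi) {
      ++right;
      const double v = x[right];
      while (!dq.empty() &&
             (want_min ? x[dq.back()] >= v : x[dq.back()] <= v))
        dq.pop_back();
      dq.push_back(right);
    }
    while (!dq.empty() && dq.front() < lo) dq.pop_front();
    out[i] = x[dq.front()];
  }
  return out;
}

// [[Rcpp::export(name = ".roll_min")]]
NumericVector roll_min(NumericVector x, int w) {
  return roll_extreme(x, w, true);
}

// [[Rcpp::export(name = ".roll_max")]]
NumericVector roll_max(NumericVector x, int w) {
  return roll_extreme(x, w, false);
}
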
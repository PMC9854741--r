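#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Trailing time-windowed running median over an irregularly sampled series.
//
// For each index i the window is (t[i] - window, t[i]]; out[i] is the median
// of x over that window when it holds at least min_count points, NA_real_
// otherwise. t must be sorted non-decreasing. Two balanced multisets give
// O(n log w); window membership is maintained with two monotone pointers so
// each point is inserted and erased exactly once.
// [[Rcpp::export]]
NumericVector roll_median_time(NumericVector t, NumericVector x,
                               double window, int min_count) {
  const int n = t.size();
  if (x.size() != n) stop("t and x must have equal length");
  NumericVector out(n, NA_REAL);
  if (n == 0) return out;

  std::multiset<double> lo, hi;  // lo holds the lower half incl. median

  auto rebalance = [&]() {
    if (lo.size() > hi.size() + 1) {
      auto it = std::prev(lo.end());
      hi.insert(*it);
      lo.erase(it);
    } else if (hi.size() > lo.size()) {
      auto it = hi.begin();
      lo.insert(*it);
      hi.erase(it);
    }
  };
  auto insert_val = [&](double v) {
    if (lo.empty() || v <= *lo.rbegin()) lo.insert(v); else hi.insert(v);
    rebalance();
  };
  auto erase_val = [&](double v) {
    auto it = lo.find(v);
    if (it != lo.end()) {
      lo.erase(it);
    } else {
      auto it2 = hi.find(v);
      if (it2 == hi.end()) stop("internal error: value not in window");
      hi.erase(it2);
    }
    rebalance();
  };

  int l = 0;  // left edge of the active window
  for (int i = 0; i < n; ++i) {
    if (i > 0 && t[i] < t[i - 1]) stop("timestamps must be sorted");
    insert_val(x[i]);
    while (t[l] <= t[i] - window) {
      erase_val(x[l]);
      ++l;
    }
    const int k = i - l + 1;
    if (k >= min_count) {
      if (k % 2 == 1) {
        out[i] = *lo.rbegin();
      } else {
        out[i] = (*lo.rbegin() + *hi.begin()) / 2.0;
      }
    }
  }
  return out;
}
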
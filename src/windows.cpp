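#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double median_of(std::vector<double> &v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double hi = v[mid];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + mid);
  return (lo + hi) / 2.0;
}

// Median of the pooled finite values, across all columns of x, whose
// positions fall within +/- half of each position. Positions must be sorted.
// With a single column this is a bp-delimited running median; with several,
// the pooled-replicate median used when combining arrays.
// [[Rcpp::export]]
NumericVector cpp_window_median(NumericVector pos, NumericMatrix x,
                                double half) {
  int n = pos.size(), k = x.ncol();
  if (x.nrow() != n) stop("pos and x must have matching length");
  NumericVector out(n);
  int lo = 0, hi = 0;
  std::vector<double> buf;
  for (int i = 0; i < n; ++i) {
    while (lo < n && pos[lo] < pos[i] - half) ++lo;
    if (hi < lo) hi = lo;
    while (hi < n && pos[hi] <= pos[i] + half) ++hi;
    buf.clear();
    for (int j = lo; j < hi; ++j)
      for (int c = 0; c < k; ++c) {
        double v = x(j, c);
        if (R_finite(v)) buf.push_back(v);
      }
    out[i] = median_of(buf);
  }
  return out;
}

// Sliding mean of values at sorted positions over half-open windows
// [q - half, q + half) for each query q (sorted not required).
// Values that are NA are excluded; windows with no finite value return NA.
// [[Rcpp::export]]
NumericVector cpp_window_mean(NumericVector pos, NumericVector val,
                              NumericVector q, double half) {
  int n = pos.size(), m = q.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double a = q[i] - half, b = q[i] + half;
    int lo = std::lower_bound(pos.begin(), pos.end(), a) - pos.begin();
    int hi = std::lower_bound(pos.begin(), pos.end(), b) - pos.begin();
    double s = 0; int cnt = 0;
    for (int j = lo; j < hi; ++j)
      if (R_finite(val[j])) { s += val[j]; ++cnt; }
    out[i] = cnt ? s / cnt : NA_REAL;
  }
  return out;
}
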
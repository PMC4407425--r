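#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exponential moving average with a per-sample smoothing constant.
// y[0] = x[0]; y[i] = y[i-1] + alpha[i] * (x[i] - y[i-1]).
// [[Rcpp::export]]
NumericVector cpp_ema(NumericVector x, NumericVector alpha) {
  int n = x.size();
  if (alpha.size() != n) stop("alpha length mismatch");
  NumericVector y(n);
  if (n == 0) return y;
  y[0] = x[0];
  for (int i = 1; i < n; ++i) {
    y[i] = y[i - 1] + alpha[i] * (x[i] - y[i - 1]);
  }
  return y;
}

// Moving baseline: mean of the top ceil(frac * m) valid values in the
// half-open window [i - window, i) of sample i (0-based, 1-s sampling),
// where m is the number of valid samples in the window. NA where m < min_n.
// [[Rcpp::export]]
NumericVector cpp_top_frac_baseline(NumericVector x, LogicalVector valid,
                                    int window, int min_n, double frac) {
  int n = x.size();
  if (valid.size() != n) stop("valid length mismatch");
  NumericVector out(n, NA_REAL);
  std::vector<double> buf;
  buf.reserve(window);
  for (int i = 0; i < n; ++i) {
    buf.clear();
    int lo = i - window;
    if (lo < 0) lo = 0;
    for (int j = lo; j < i; ++j) {
      if (valid[j]) buf.push_back(x[j]);
    }
    int m = (int)buf.size();
    if (m < min_n) continue;
    int k = (int)std::ceil(frac * m);
    if (k < 1) k = 1;
    std::partial_sort(buf.begin(), buf.begin() + k, buf.end(),
                      std::greater<double>());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += buf[j];
    out[i] = s / k;
  }
  return out;
}
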
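#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Centered rolling percentile with truncated edge windows.
// The window at position i covers [i - floor((w-1)/2), i + ceil((w-1)/2)]
// clipped to the trace; the percentile uses the linear-interpolation
// definition (R quantile type 7) on the window's sorted values.
// [[Rcpp::export]]
NumericVector rolling_percentile_cpp(NumericVector x, int window,
                                     double prob) {
  int n = x.size();
  if (window < 1) stop("window must be >= 1");
  if (prob <= 0.0 || prob >= 1.0) stop("prob must be in (0, 1)");
  int lo_off = (window - 1) / 2;
  int hi_off = window - 1 - lo_off;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(window);
  for (int i = 0; i < n; ++i) {
    int a = std::max(0, i - lo_off);
    int b = std::min(n - 1, i + hi_off);
    int m = b - a + 1;
    buf.assign(x.begin() + a, x.begin() + b + 1);
    double h = (m - 1) * prob;
    int k = (int)std::floor(h);
    double frac = h - k;
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double vk = buf[k];
    if (frac > 0.0 && k + 1 < m) {
      double vk1 = *std::min_element(buf.begin() + k + 1, buf.end());
      out[i] = vk + frac * (vk1 - vk);
    } else {
      out[i] = vk;
    }
  }
  return out;
}
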
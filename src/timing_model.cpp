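#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form expected replication time per site under exponential origin
// firing and constant-speed bidirectional forks:
//
//   E[T_j] = sum_{k=0}^{R} [ exp(-S_k/v) - exp(-(S_k + W_k)/v) ] / W_k
//
// with W_k = sum_{|i|<=k} f_{j+i} and S_k = sum_{|i|<=k} (k-|i|) f_{j+i},
// maintained by the recurrences W_{k+1} = W_k + f_{j-k-1} + f_{j+k+1},
// S_{k+1} = S_k + W_k. Out-of-range neighbours contribute rate 0 (clamped
// chromosome ends); with `circular`, indices wrap modulo n and k is capped
// at floor((n-1)/2) so the window never overlaps itself.
//
// The k-th term is evaluated as exp(-S_k/v) * (-expm1(-W_k/v)) / W_k for
// numerical stability; when W_k underflows the analytic limit
// exp(-S_k/v)/v is used (1/v when no origin lies within range k). The sum
// stops early once exp(-S_k/v) < tail_tol, since every later term is
// bounded by exp(-S_k/v)/v and S_k is non-decreasing.
// [[Rcpp::export]]
NumericVector cpp_expected_timing(NumericVector rates, double v, int R,
                                  double tail_tol, bool circular) {
  const int n = rates.size();
  NumericVector out(n);
  int kmax = R;
  if (circular) {
    int half = (n - 1) / 2;
    if (kmax > half) kmax = half;
  }
  const double wtiny = 1e-300;
  const double s_stop = -v * std::log(tail_tol);
  for (int j = 0; j < n; ++j) {
    double W = rates[j], S = 0.0, sum = 0.0;
    for (int k = 0; k <= kmax; ++k) {
      if (k > 0 && S > s_stop) break;
      double eS = std::exp(-S / v);
      double term = (W > wtiny) ? eS * (-std::expm1(-W / v)) / W : eS / v;
      sum += term;
      S += W;
      long il = (long)j - k - 1, ir = (long)j + k + 1;
      double fl = 0.0, fr = 0.0;
      if (circular) {
        il = ((il % n) + n) % n;
        ir = ir % n;
        fl = rates[il];
        fr = rates[ir];
      } else {
        if (il >= 0) fl = rates[il];
        if (ir < n) fr = rates[ir];
      }
      W += fl + fr;
    }
    out[j] = sum;
  }
  return out;
}
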
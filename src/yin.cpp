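#include <Rcpp.h>
using namespace Rcpp;

// Cumulative-mean-normalized difference function (CMND) of the YIN pitch
// estimator. d(tau) = sum_t (x[t] - x[t+tau])^2 over the first half of the
// frame; CMND(tau) = d(tau) * tau / sum_{j<=tau} d(j), CMND(0) = 1.
// Returns CMND for tau = 1 .. max_lag. The frame must satisfy
// 2 * max_lag <= n so every lag uses the same integration length.
// [[Rcpp::export]]
NumericVector yin_cmnd(NumericVector x, int max_lag) {
  int n = x.size();
  if (max_lag < 1) stop("max_lag must be >= 1");
  if (2 * max_lag > n) stop("frame too short for max_lag");
  int w = n - max_lag;  // integration window, identical for all lags
  NumericVector d(max_lag), cmnd(max_lag);
  double run = 0.0;
  for (int tau = 1; tau <= max_lag; ++tau) {
    double acc = 0.0;
    const double* p = REAL(x);
    for (int t = 0; t < w; ++t) {
      double diff = p[t] - p[t + tau];
      acc += diff * diff;
    }
    d[tau - 1] = acc;
    run += acc;
    cmnd[tau - 1] = (run > 0.0) ? acc * tau / run : 1.0;
  }
  return cmnd;
}
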
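#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sliding sums for one ramp component w * (1 - (i-1)/m) over lags 1..m:
// contribution at step t is w * (A - B/m) with A = sum_{i=1..m} x_{t-i} and
// B = sum_{i=1..m} (i-1) x_{t-i}, both updated in O(1) per step.
struct Ramp {
  double w;
  int m;
  double A = 0.0, B = 0.0;
  double value() const { return w * (A - B / m); }
  void push(const std::vector<double>& x, int t) {  // after computing step t
    B += A - (t - m >= 0 ? m * x[t - m] : 0.0);
    A += x[t] - (t - m >= 0 ? x[t - m] : 0.0);
  }
};

// Causal pass of the serial-history model over one session.
// high_level: 1 = high-contrast stimulus, 0 = low. Tracks one midpoint
// sequence per judged-test contrast; each uses its own components and
// k_norm = 2 ln(9) / k. Low-contrast past stimuli are down-weighted by
// 1/gamma. Returns the probability of "orange" for test rows (NA on
// adaptors) and both midpoint tracks.
// [[Rcpp::export]]
List linear_predict_cpp(NumericVector theta, IntegerVector high_level,
                        IntegerVector is_test, double c0, double k_high,
                        double k_low, NumericVector w_high,
                        IntegerVector m_high, NumericVector w_low,
                        IntegerVector m_low, double gamma) {
  const int n = theta.size();
  std::vector<Ramp> rh(w_high.size()), rl(w_low.size());
  for (int k = 0; k < w_high.size(); ++k) rh[k] = Ramp{w_high[k], m_high[k]};
  for (int k = 0; k < w_low.size(); ++k) rl[k] = Ramp{w_low[k], m_low[k]};
  const double knh = 2.0 * std::log(9.0) / k_high;
  const double knl = 2.0 * std::log(9.0) / k_low;

  NumericVector ch(n), cl(n), p(n, NA_REAL);
  std::vector<double> xh(n), xl(n);  // s_j * (c_j - theta_j) per track
  for (int t = 0; t < n; ++t) {
    double sh = 0.0, sl = 0.0;
    for (const Ramp& r : rh) sh += r.value();
    for (const Ramp& r : rl) sl += r.value();
    ch[t] = c0 + knh * sh;
    cl[t] = c0 + knl * sl;
    const double sfac = high_level[t] ? 1.0 : 1.0 / gamma;
    xh[t] = sfac * (ch[t] - theta[t]);
    xl[t] = sfac * (cl[t] - theta[t]);
    for (Ramp& r : rh) r.push(xh, t);
    for (Ramp& r : rl) r.push(xl, t);
    if (is_test[t]) {
      const double k = high_level[t] ? k_high : k_low;
      const double c = high_level[t] ? ch[t] : cl[t];
      p[t] = 1.0 / (1.0 + std::exp(-k * (theta[t] - c)));
    }
  }
  return List::create(_["p"] = p, _["c_high"] = ch, _["c_low"] = cl);
}
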
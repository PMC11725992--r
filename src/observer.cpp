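#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sequential Bayesian channel-adaptation observer over one ordered session.
//
// Per stimulus, in order: (1) gains recover toward 1 with the time elapsed
// since the previous stimulus offset; (2) channel responses from the
// contrast-gain and tuning-width functions (both rescaled so contrast 1
// reproduces the maximum-contrast tuning curve); (3) orientation likelihood
// exp(omega_s * sum_i m_i n_i log phi_i) normalised over the grid, with
// omega_s = omega * duration / 0.3; (4) posterior = likelihood x prior;
// (5) for tests, p("orange") from the ROC area between posterior and the
// reference distribution, P(X>Y) + P(X=Y)/2 on the shared grid ordered
// counterclockwise from the reference mean; (6) gains adapt by
// m_i *= (1 - alpha n_i); (7) prior <- (1-tau) prior + tau posterior.
//
// logPhi is the G x N matrix of log tuning curves (maximum contrast) on the
// grid; ref_rank[g] gives, for grid index g, the reference CDF ordering
// statistic C(g) - ref(g)/2 precomputed in R.
// [[Rcpp::export]]
List observer_simulate_cpp(NumericVector theta, NumericVector contrast,
                           NumericVector duration, NumericVector onset,
                           IntegerVector is_test, NumericVector mu,
                           double kappa_phi, double c50, double cexp,
                           double w50, double weps, int cv, double alpha,
                           double beta, double tau, double omega,
                           NumericMatrix logPhi, NumericVector ref_stat,
                           bool trace) {
  const int n = theta.size();
  const int N = mu.size();
  const int G = logPhi.nrow();
  const double DEG2 = 2.0 * M_PI / 180.0;  // degrees -> double-angle radians

  std::vector<double> gains(N, 1.0), prior(G, 1.0 / G);
  std::vector<double> resp(N), loglik(G), lik(G), post(G);
  const double nr1 = 1.0 / (std::pow(c50, cexp) + 1.0);   // gain at c = 1
  const double sw1 = 1.0 / (std::pow(w50, weps) + 1.0);   // width sat at c = 1

  NumericVector p(n, NA_REAL);
  NumericMatrix gain_trace;
  NumericVector lik_mode(0), post_mode(0);
  if (trace) {
    gain_trace = NumericMatrix(n, N);
    lik_mode = NumericVector(n);
    post_mode = NumericVector(n);
  }

  for (int t = 0; t < n; ++t) {
    if (t > 0) {  // recovery runs only between presentations
      double dt = onset[t] - onset[t - 1] - duration[t - 1];
      double r = std::min(beta * std::max(dt, 0.0), 1.0);
      for (int i = 0; i < N; ++i) gains[i] = gains[i] * (1.0 - r) + r;
    }
    const double c = contrast[t];
    const double gain =
        (std::pow(c, cexp) / (std::pow(c50, cexp) + std::pow(c, cexp))) / nr1;
    double kc = kappa_phi;
    if (cv)
      kc = kappa_phi *
           (std::pow(c, weps) / (std::pow(w50, weps) + std::pow(c, weps))) / sw1;
    for (int i = 0; i < N; ++i)
      resp[i] = gain * std::exp(kc * (std::cos(DEG2 * (theta[t] - mu[i])) - 1.0));

    // decoding uses tuning at the stimulus's contrast: log phi scales by
    // kc / kappa_phi, folded into the accumulation factor
    const double ws = omega * duration[t] / 0.3 * kc / kappa_phi;
    double mx = -INFINITY;
    for (int g = 0; g < G; ++g) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += logPhi(g, i) * gains[i] * resp[i];
      loglik[g] = ws * s;
      if (loglik[g] > mx) mx = loglik[g];
    }
    double zl = 0.0, zp = 0.0;
    for (int g = 0; g < G; ++g) {
      lik[g] = std::exp(loglik[g] - mx);
      zl += lik[g];
    }
    for (int g = 0; g < G; ++g) {
      lik[g] /= zl;
      post[g] = lik[g] * prior[g];
      zp += post[g];
    }
    if (zp <= 0.0) stop("posterior has zero total mass at stimulus %d", t + 1);
    for (int g = 0; g < G; ++g) post[g] /= zp;

    if (is_test[t]) {
      double s = 0.0;
      for (int g = 0; g < G; ++g) s += post[g] * ref_stat[g];
      p[t] = s;
    }

    for (int i = 0; i < N; ++i) gains[i] *= (1.0 - alpha * resp[i]);
    for (int g = 0; g < G; ++g)
      prior[g] = (1.0 - tau) * prior[g] + tau * post[g];

    if (trace) {
      for (int i = 0; i < N; ++i) gain_trace(t, i) = gains[i];
      int gm = 0, pm = 0;
      for (int g = 1; g < G; ++g) {
        if (lik[g] > lik[gm]) gm = g;
        if (post[g] > post[pm]) pm = g;
      }
      lik_mode[t] = gm + 1;   // 1-based grid index
      post_mode[t] = pm + 1;
    }
  }

  List out = List::create(_["p"] = p,
                          _["gains"] = NumericVector(gains.begin(), gains.end()),
                          _["prior"] = NumericVector(prior.begin(), prior.end()));
  if (trace) {
    out["gain_trace"] = gain_trace;
    out["lik_mode"] = lik_mode;
    out["post_mode"] = post_mode;
  }
  return out;
}
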
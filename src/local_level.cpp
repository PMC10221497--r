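#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the Bayesian local-level model
//   y_t = mu_t + eps_t,  eps_t ~ N(0, s2_obs)
//   mu_{t+1} = mu_t + eta_t,  eta_t ~ N(0, s2_level)
// alternating (a) a level-path draw by forward-filter backward-sampling and
// (b) inverse-gamma conjugate draws of both variances. Uses R's RNG.

static inline double rinvgamma(double shape, double rate) {
  return rate / R::rgamma(shape, 1.0);
}

// [[Rcpp::export]]
List ll_gibbs_cpp(NumericVector y, int n_chains, int n_iter, int burn_in,
                  double a0, double b0, double m0, double P0,
                  double var_floor) {
  int n = y.size();
  int kept_per_chain = n_iter - burn_in;
  int total = n_chains * kept_per_chain;
  NumericVector s2_obs_d(total), s2_level_d(total), level_T_d(total);
  IntegerVector chain_d(total);

  std::vector<double> m(n), P(n), mu(n);
  double y_var = 0.0, y_mean = 0.0;
  for (int t = 0; t < n; ++t) y_mean += y[t];
  y_mean /= n;
  for (int t = 0; t < n; ++t) y_var += (y[t] - y_mean) * (y[t] - y_mean);
  y_var = n > 1 ? y_var / (n - 1) : 1.0;
  if (y_var <= 0) y_var = var_floor;

  int idx = 0;
  for (int ch = 0; ch < n_chains; ++ch) {
    // overdispersed-ish starts spread over chains
    double s2_obs = y_var * (0.5 + ch * 0.5);
    double s2_level = y_var * 0.1 * (0.5 + ch * 0.5);

    for (int it = 0; it < n_iter; ++it) {
      // forward filter
      double m_prev = m0, P_prev = P0;
      for (int t = 0; t < n; ++t) {
        double P_pred = P_prev + (t == 0 ? 0.0 : s2_level);
        double S = P_pred + s2_obs;
        double K = P_pred / S;
        m[t] = m_prev + K * (y[t] - m_prev);
        P[t] = (1.0 - K) * P_pred;
        m_prev = m[t];
        P_prev = P[t];
      }
      // backward sample
      mu[n - 1] = R::rnorm(m[n - 1], std::sqrt(std::max(P[n - 1], 0.0)));
      for (int t = n - 2; t >= 0; --t) {
        double denom = P[t] + s2_level;
        double h = denom > 0 ? P[t] / denom : 0.0;
        double mean = m[t] + h * (mu[t + 1] - m[t]);
        double v = P[t] * (1.0 - h);
        mu[t] = R::rnorm(mean, std::sqrt(std::max(v, 0.0)));
      }
      // conjugate variance draws
      double sse_obs = 0.0, sse_level = 0.0;
      for (int t = 0; t < n; ++t) sse_obs += (y[t] - mu[t]) * (y[t] - mu[t]);
      for (int t = 1; t < n; ++t) sse_level += (mu[t] - mu[t - 1]) * (mu[t] - mu[t - 1]);
      s2_obs = rinvgamma(a0 + 0.5 * n, b0 + 0.5 * sse_obs);
      s2_level = rinvgamma(a0 + 0.5 * (n - 1), b0 + 0.5 * sse_level);
      if (s2_obs < var_floor) s2_obs = var_floor;
      if (s2_level < var_floor) s2_level = var_floor;

      if (it >= burn_in) {
        s2_obs_d[idx] = s2_obs;
        s2_level_d[idx] = s2_level;
        level_T_d[idx] = mu[n - 1];
        chain_d[idx] = ch + 1;
        ++idx;
      }
      if (it % 200 == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["s2_obs"] = s2_obs_d, _["s2_level"] = s2_level_d,
                      _["level_T"] = level_T_d, _["chain"] = chain_d);
}
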
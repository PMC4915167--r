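#include <Rcpp.h>
using namespace Rcpp;

// BayesC Gibbs sampler with per-record residual weights.
//
// Model: y_i = mu + sum_j z_ij a_j delta_j + e_i,  e_i ~ N(0, sigma2_e / w_i)
// delta_j ~ Bernoulli(pi); a_j | delta_j = 1 ~ N(0, sigma2_a);
// sigma2_a, sigma2_e ~ scaled-inverse-chi-square(df, scale).
//
// Per iteration: mu from its weighted normal conditional (flat prior); for
// each marker, delta_j from the marginalized Bernoulli conditional (effect
// integrated out) then a_j from its normal conditional when included;
// variances from their scaled-inv-chi2 conditionals unless held fixed.
// Markers are updated in fixed map order; the whole chain draws from R's RNG
// so runs are bit-reproducible under set.seed().
//
// The weighted residual we_i = w_i * e_i is maintained alongside e so the
// per-marker right-hand side z_j' W e is a plain two-stream dot product.
//
// [[Rcpp::export]]
List bayesc_gibbs(const NumericMatrix& Z, const NumericVector& y,
                  const NumericVector& w, double pi_prior,
                  int n_iter, int burn_in, int thin,
                  double df_a, double scale_a, double df_e, double scale_e,
                  bool update_sigma_a, bool update_sigma_e,
                  double sigma2_a_init, double sigma2_e_init) {
  const int n = Z.nrow(), m = Z.ncol();
  const double* Zp = &Z(0, 0);
  const double* wp = &w[0];
  std::vector<double> a(m, 0.0), e(n), we(n);
  std::vector<int> delta(m, 0);
  double mu = 0.0, sw = 0.0;
  for (int i = 0; i < n; ++i) sw += wp[i];
  for (int i = 0; i < n; ++i) mu += wp[i] * y[i];
  mu /= sw;
  for (int i = 0; i < n; ++i) {
    e[i] = y[i] - mu;
    we[i] = wp[i] * e[i];
  }

  // z' W z per marker is constant across iterations
  std::vector<double> zwz(m);
  for (int j = 0; j < m; ++j) {
    const double* zj = Zp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += wp[i] * zj[i] * zj[i];
    zwz[j] = s;
  }

  double s2a = sigma2_a_init, s2e = sigma2_e_init;
  const bool always_in = pi_prior >= 1.0;
  const double log_prior_odds =
      always_in ? 0.0 : std::log(pi_prior / (1.0 - pi_prior));

  const int n_kept_max = (n_iter - burn_in + thin - 1) / thin;
  std::vector<double> incl(m, 0.0), eff_sum(m, 0.0);
  NumericVector chain_mu(n_kept_max), chain_s2a(n_kept_max),
      chain_s2e(n_kept_max);
  IntegerVector chain_nin(n_kept_max), chain_iter(n_kept_max);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // mu | rest (flat prior)
    double r_mu = 0.0;
    for (int i = 0; i < n; ++i) r_mu += we[i];
    r_mu += sw * mu;
    const double mu_new = R::rnorm(r_mu / sw, std::sqrt(s2e / sw));
    const double dmu = mu - mu_new;
    for (int i = 0; i < n; ++i) {
      e[i] += dmu;
      we[i] += wp[i] * dmu;
    }
    mu = mu_new;

    int n_in = 0;
    double ssa = 0.0;
    for (int j = 0; j < m; ++j) {
      const double* zj = Zp + (size_t)j * n;
      if (delta[j]) { // restore residuals without marker j
        const double aj = a[j];
        for (int i = 0; i < n; ++i) {
          e[i] += zj[i] * aj;
          we[i] += wp[i] * zj[i] * aj;
        }
      }
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += zj[i] * we[i];
      const double C = zwz[j] / s2e + 1.0 / s2a;
      bool in;
      if (always_in) {
        in = true;
      } else {
        const double log_odds = log_prior_odds - 0.5 * std::log(s2a * C) +
                                0.5 * r * r / (s2e * s2e * C);
        const double u = unif_rand();
        in = std::log(u / (1.0 - u)) < log_odds;
      }
      if (in) {
        const double aj = R::rnorm(r / (s2e * C), std::sqrt(1.0 / C));
        a[j] = aj;
        delta[j] = 1;
        for (int i = 0; i < n; ++i) {
          e[i] -= zj[i] * aj;
          we[i] -= wp[i] * zj[i] * aj;
        }
        ++n_in;
        ssa += aj * aj;
      } else {
        a[j] = 0.0;
        delta[j] = 0;
      }
    }

    if (update_sigma_a) {
      s2a = (df_a * scale_a + ssa) / R::rchisq(df_a + n_in);
    }
    if (update_sigma_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += we[i] * e[i];
      s2e = (df_e * scale_e + sse) / R::rchisq(df_e + n);
    }

    if (it > burn_in && ((it - burn_in - 1) % thin == 0)) {
      for (int j = 0; j < m; ++j) {
        incl[j] += delta[j];
        eff_sum[j] += a[j]; // a[j] is zero when excluded
      }
      chain_mu[kept] = mu;
      chain_s2a[kept] = s2a;
      chain_s2e[kept] = s2e;
      chain_nin[kept] = n_in;
      chain_iter[kept] = it;
      ++kept;
    }
  }

  NumericVector P(m), mean_effect(m);
  for (int j = 0; j < m; ++j) {
    P[j] = incl[j] / kept;
    mean_effect[j] = eff_sum[j] / kept;
  }
  return List::create(
      _["P"] = P, _["mean_effect"] = mean_effect, _["n_kept"] = kept,
      _["chain_iter"] = chain_iter, _["chain_mu"] = chain_mu,
      _["chain_sigma2_a"] = chain_s2a, _["chain_sigma2_e"] = chain_s2e,
      _["chain_n_included"] = chain_nin);
}
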
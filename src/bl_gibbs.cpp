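#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Inverse-Gaussian sampler (Michael-Schucany-Haas), using R's RNG so the
// chain is reproducible under set.seed().
static double rinvgauss(double mu, double lam) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lam) -
    (mu / (2.0 * lam)) * std::sqrt(4.0 * mu * lam * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double z = R::unif_rand();
  return (z <= mu / (mu + x)) ? x : mu * mu / x;
}

// Gibbs sampler for the Bayesian LASSO (Park-Casella hierarchy):
// y = 1 beta + Z a + e, a_j | tau_j^2, s2e ~ N(0, tau_j^2 s2e),
// tau_j^2 ~ Exp(rate lambda^2 / 2), lambda^2 ~ Gamma(r, delta),
// s2e ~ scaled-inv-chi2(df_e, S_e).
// [[Rcpp::export(name = ".bl_gibbs_cpp")]]
List bl_gibbs_cpp(const arma::vec& y, const arma::mat& Z,
                  int chain, int burnin, int thin,
                  double df_e, double S_e, double prior_r, double prior_delta,
                  double lambda2_init, bool fix_lambda2) {
  const int n = y.n_elem, p = Z.n_cols;
  arma::vec ztz(p);
  for (int j = 0; j < p; ++j) ztz(j) = arma::dot(Z.col(j), Z.col(j));

  double beta = arma::mean(y);
  arma::vec a(p, arma::fill::zeros);
  arma::vec tau2(p, arma::fill::ones);
  double lambda2 = lambda2_init;
  double s2e = arma::var(y) * 0.5;
  arma::vec e = y - beta;

  arma::vec a_sum(p, arma::fill::zeros);
  arma::vec gebv_sum(n, arma::fill::zeros);
  arma::vec tau2_sum(p, arma::fill::zeros);
  double beta_sum = 0.0, s2e_sum = 0.0, lambda2_sum = 0.0;
  int kept = 0;
  std::vector<double> s2e_draws;

  for (int it = 1; it <= chain; ++it) {
    // intercept
    double bnew = beta + arma::mean(e) +
      R::norm_rand() * std::sqrt(s2e / n);
    e -= (bnew - beta);
    beta = bnew;
    // marker effects, coordinate-wise
    for (int j = 0; j < p; ++j) {
      double old = a(j);
      double num = arma::dot(Z.col(j), e) + ztz(j) * old;
      double dj = ztz(j) + 1.0 / tau2(j);
      double mean = num / dj;
      double anew = mean + R::norm_rand() * std::sqrt(s2e / dj);
      if (anew != old) e -= Z.col(j) * (anew - old);
      a(j) = anew;
    }
    // tau^2
    for (int j = 0; j < p; ++j) {
      double aj2 = a(j) * a(j);
      double mu = (aj2 > 1e-14 * s2e) ?
        std::sqrt(lambda2 * s2e / aj2) : 1e7;
      if (mu > 1e7) mu = 1e7;
      double inv_t2 = rinvgauss(mu, lambda2);
      tau2(j) = 1.0 / std::max(inv_t2, 1e-12);
    }
    // lambda^2
    if (!fix_lambda2) {
      double shape = p + prior_r;
      double rate = prior_delta + arma::accu(tau2) / 2.0;
      lambda2 = R::rgamma(shape, 1.0 / rate);
    }
    // residual variance
    double sc = S_e + arma::dot(e, e) + arma::accu(a % a / tau2);
    double chi = R::rchisq(df_e + n + p);
    s2e = sc / std::max(chi, 1e-12);
    if (!std::isfinite(s2e) || !a.is_finite())
      stop("Bayesian LASSO chain diverged at iteration %d", it);

    if (it > burnin && (it - burnin) % thin == 0) {
      ++kept;
      a_sum += a;
      gebv_sum += Z * a;
      tau2_sum += tau2;
      beta_sum += beta;
      s2e_sum += s2e;
      lambda2_sum += lambda2;
      s2e_draws.push_back(s2e);
    }
  }
  if (kept == 0) stop("no retained samples: check chain/burnin/thin");
  return List::create(
    _["beta"] = beta_sum / kept,
    _["a"] = a_sum / kept,
    _["gebv"] = gebv_sum / kept,
    _["tau2"] = tau2_sum / kept,
    _["sigma2_e"] = s2e_sum / kept,
    _["lambda2"] = lambda2_sum / kept,
    _["n_retained"] = kept,
    _["s2e_draws"] = s2e_draws);
}
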
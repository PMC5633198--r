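// BayesC Gibbs sampler for the haplotype-block regression
//   y_i = mu + sum_j r_j I_ij + e
// with a spike-and-slab prior on block effects: each effect is zero with
// probability pi, otherwise drawn from a common N(0, s2b) slab. Scaled
// inverse-chi-square priors on s2b and the residual variance; optional
// Beta prior on pi. Uses R's RNG so results are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvchisq(double nu, double scale) {
  // scaled inverse chi-square draw: nu * scale / chisq(nu)
  return nu * scale / R::rchisq(nu);
}

// [[Rcpp::export(name = ".bayesc_gibbs")]]
List bayesc_gibbs(const arma::mat& X, const arma::vec& y,
                  int n_iter, int burn_in,
                  double pi_init, bool estimate_pi,
                  double pi_a, double pi_b,
                  double nu_b, double scale_b,
                  double nu_e, double scale_e) {
  const int n = X.n_rows, m = X.n_cols;
  arma::vec xtx(m);
  for (int j = 0; j < m; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  double mu = arma::mean(y);
  arma::vec beta(m, arma::fill::zeros);
  arma::uvec delta(m, arma::fill::zeros);
  double s2b = nu_b * scale_b / std::max(nu_b - 2.0, 0.5); // prior mean-ish
  double s2e = nu_e * scale_e / std::max(nu_e - 2.0, 0.5);
  double pi = pi_init;

  arma::vec e = y - mu;

  arma::vec beta_sum(m, arma::fill::zeros);
  arma::vec incl_sum(m, arma::fill::zeros);
  double mu_sum = 0, s2b_sum = 0, s2e_sum = 0, pi_sum = 0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    e += mu;
    double mhat = arma::mean(e);
    mu = R::rnorm(mhat, std::sqrt(s2e / n));
    e -= mu;

    // block effects (single-site updates, slab integrated for the indicator)
    int m_in = 0;
    for (int j = 0; j < m; ++j) {
      if (xtx(j) <= 0) { beta(j) = 0; delta(j) = 0; continue; }
      if (delta(j)) e += X.col(j) * beta(j);
      double rhs = arma::dot(X.col(j), e);
      double v1 = xtx(j) * s2b + s2e;
      double logBF = 0.5 * (rhs * rhs * s2b / (s2e * v1)) -
                     0.5 * std::log(v1 / s2e);
      double lodds = std::log(1.0 - pi) - std::log(pi) + logBF;
      double p1 = 1.0 / (1.0 + std::exp(-lodds));
      if (R::unif_rand() < p1) {
        double C = xtx(j) + s2e / s2b;
        double bhat = rhs / C;
        beta(j) = R::rnorm(bhat, std::sqrt(s2e / C));
        e -= X.col(j) * beta(j);
        delta(j) = 1;
        ++m_in;
      } else {
        beta(j) = 0;
        delta(j) = 0;
      }
    }

    // slab variance
    double ssb = 0;
    for (int j = 0; j < m; ++j) if (delta(j)) ssb += beta(j) * beta(j);
    s2b = rinvchisq(nu_b + m_in, (ssb + nu_b * scale_b) / (nu_b + m_in));

    // residual variance
    double sse = arma::dot(e, e);
    s2e = rinvchisq(nu_e + n, (sse + nu_e * scale_e) / (nu_e + n));

    // exclusion probability
    if (estimate_pi) {
      pi = R::rbeta(pi_a + (m - m_in), pi_b + m_in);
      pi = std::min(std::max(pi, 1e-6), 1.0 - 1e-6);
    }

    if (it >= burn_in) {
      beta_sum += beta;
      for (int j = 0; j < m; ++j) incl_sum(j) += delta(j);
      mu_sum += mu; s2b_sum += s2b; s2e_sum += s2e; pi_sum += pi;
      ++kept;
    }
  }

  return List::create(
    _["mu"] = mu_sum / kept,
    _["beta"] = NumericVector(beta_sum.begin(), beta_sum.end()) / kept,
    _["inclusion"] = NumericVector(incl_sum.begin(), incl_sum.end()) / kept,
    _["s2b"] = s2b_sum / kept,
    _["s2e"] = s2e_sum / kept,
    _["pi"] = pi_sum / kept,
    _["n_kept"] = kept);
}
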
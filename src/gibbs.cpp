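// Gibbs samplers for single-trait and multi-trait GBLUP with a genomic
// relationship matrix K = U diag(d) U'. Both samplers work in the rotated
// basis (genetic values alpha = U gamma), where the single-trait update is
// diagonal and the multi-trait update factorizes into one t x t solve per
// eigen-coordinate. Missing phenotypes are handled by data augmentation.
//
// All randomness comes from R's RNG (norm_rand / rchisq), so set.seed() in R
// gives bit-identical chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double rnorm1() { return ::norm_rand(); }
static inline double rchisq1(double df) { return ::Rf_rchisq(df); }

// Wishart(df, S) via Bartlett decomposition: W = L A A' L', chol(S) = L L'
static arma::mat rwishart(double df, const arma::mat& S) {
  const arma::uword t = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(t, t, arma::fill::zeros);
  for (arma::uword i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(rchisq1(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// inverse-Wishart(df, Psi); jitters Psi if its Cholesky fails
static arma::mat riwishart(double df, const arma::mat& Psi, bool& jittered) {
  arma::mat Psi_inv;
  arma::mat P = Psi;
  for (int attempt = 0; attempt < 5; ++attempt) {
    if (arma::inv_sympd(Psi_inv, P)) {
      arma::mat W = rwishart(df, Psi_inv);
      arma::mat Sigma;
      if (arma::inv_sympd(Sigma, W)) return Sigma;
    }
    jittered = true;
    P += arma::eye(P.n_rows, P.n_cols) * (1e-8 * (1.0 + arma::trace(P) / P.n_rows));
  }
  stop("inverse-Wishart draw failed after jittering");
}

// [[Rcpp::export(name = ".gibbs_st_cpp")]]
List gibbs_st_cpp(const arma::vec& y, const arma::uvec& obs,
                  const arma::mat& U, const arma::vec& d,
                  int burn_in, int n_iter, int thin,
                  double nu0, double s0g, double s0e,
                  double fix_g, double fix_e, bool keep_alpha) {
  const arma::uword n = y.n_elem;
  const double dtol = 1e-10 * d.max();
  arma::uvec pos = arma::find(d > dtol);
  arma::uvec mis = arma::find(obs == 0);
  arma::uvec iobs = arma::find(obs == 1);
  const double npos = (double)pos.n_elem;

  arma::vec yo = y.elem(iobs);
  double mu = arma::mean(yo);
  double vy = arma::var(yo);
  double s2g = (fix_g > 0) ? fix_g : vy / 2.0;
  double s2e = (fix_e > 0) ? fix_e : vy / 2.0;

  arma::vec gamma(n, arma::fill::zeros), alpha(n, arma::fill::zeros);
  arma::vec y_aug = y;
  y_aug.elem(mis).fill(mu);
  arma::mat Ut = U.t();

  const int n_keep = (n_iter - burn_in) / thin;
  arma::vec sum_alpha(n, arma::fill::zeros), sum_pred(n, arma::fill::zeros);
  double sum_mu = 0, sum_g = 0, sum_e = 0;
  arma::vec ch_g(n_keep), ch_e(n_keep), ch_mu(n_keep), ch_ll(n_keep);
  arma::mat ch_alpha;
  if (keep_alpha) ch_alpha.set_size(n_keep, n);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    alpha = U * gamma;
    // data augmentation for missing phenotypes
    for (arma::uword k = 0; k < mis.n_elem; ++k) {
      arma::uword i = mis(k);
      y_aug(i) = mu + alpha(i) + rnorm1() * std::sqrt(s2e);
    }
    // intercept
    mu = arma::mean(y_aug - alpha) + rnorm1() * std::sqrt(s2e / (double)n);
    // genetic values in the eigen basis (diagonal update)
    arma::vec yt = Ut * (y_aug - mu);
    double ssq = 0;
    for (arma::uword k = 0; k < pos.n_elem; ++k) {
      arma::uword i = pos(k);
      double v = 1.0 / (1.0 / s2e + 1.0 / (d(i) * s2g));
      gamma(i) = v * yt(i) / s2e + std::sqrt(v) * rnorm1();
      ssq += gamma(i) * gamma(i) / d(i);
    }
    // variance components (scaled-inverse-chi-square conditionals)
    if (fix_g <= 0) s2g = (nu0 * s0g + ssq) / rchisq1(nu0 + npos);
    alpha = U * gamma;
    arma::vec resid = y_aug - mu - alpha;
    if (fix_e <= 0)
      s2e = (nu0 * s0e + arma::dot(resid, resid)) / rchisq1(nu0 + (double)n);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      sum_alpha += alpha;
      sum_pred += mu + alpha;
      sum_mu += mu; sum_g += s2g; sum_e += s2e;
      ch_g(kept) = s2g; ch_e(kept) = s2e; ch_mu(kept) = mu;
      arma::vec ro = resid.elem(iobs);
      ch_ll(kept) = -0.5 * (double)iobs.n_elem * std::log(2.0 * M_PI * s2e)
                    - 0.5 * arma::dot(ro, ro) / s2e;
      if (keep_alpha) ch_alpha.row(kept) = alpha.t();
      ++kept;
    }
  }

  List chains = List::create(_["sigma2_g"] = ch_g, _["sigma2_e"] = ch_e,
                             _["mu"] = ch_mu, _["loglik"] = ch_ll);
  if (keep_alpha) chains["alpha"] = ch_alpha;
  return List::create(
    _["mu_hat"] = sum_mu / kept,
    _["alpha_hat"] = sum_alpha / kept,
    _["pred_hat"] = sum_pred / kept,
    _["sigma2_g_hat"] = sum_g / kept,
    _["sigma2_e_hat"] = sum_e / kept,
    _["chains"] = chains);
}

// [[Rcpp::export(name = ".gibbs_mt_cpp")]]
List gibbs_mt_cpp(const arma::mat& Y, const arma::umat& obs,
                  const arma::mat& U, const arma::vec& d,
                  int burn_in, int n_iter, int thin,
                  double nuR, const arma::vec& s0R,
                  double nuS, const arma::mat& S0,
                  bool keep_sigma_chain) {
  const arma::uword n = Y.n_rows, t = Y.n_cols;
  const double dtol = 1e-10 * d.max();
  arma::uvec pos = arma::find(d > dtol);
  const double npos = (double)pos.n_elem;

  arma::vec mu(t), Rv(t);
  arma::mat Yaug = Y;
  for (arma::uword j = 0; j < t; ++j) {
    arma::uvec oj = arma::find(obs.col(j) == 1);
    arma::vec yo = Y.col(j);
    mu(j) = arma::mean(yo.elem(oj));
    Rv(j) = arma::var(yo.elem(oj)) / 2.0;
    for (arma::uword i = 0; i < n; ++i) if (!obs(i, j)) Yaug(i, j) = mu(j);
  }
  arma::mat Sigma = arma::diagmat(Rv);  // init at half the trait variances
  arma::mat Gamma(n, t, arma::fill::zeros), A(n, t, arma::fill::zeros);
  arma::mat Ut = U.t();
  int n_jitter = 0;

  const int n_keep = (n_iter - burn_in) / thin;
  arma::vec sum_mu(t, arma::fill::zeros), sum_R(t, arma::fill::zeros);
  arma::mat sum_A(n, t, arma::fill::zeros), sum_pred(n, t, arma::fill::zeros);
  arma::mat sum_Sigma(t, t, arma::fill::zeros);
  arma::mat ch_Sigma, ch_R(n_keep, t), ch_mu(n_keep, t);
  arma::vec ch_ll(n_keep);
  if (keep_sigma_chain) ch_Sigma.set_size(n_keep, t * t);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    A = U * Gamma;
    // data augmentation (R diagonal => cells independent given A)
    for (arma::uword j = 0; j < t; ++j) {
      double sj = std::sqrt(Rv(j));
      for (arma::uword i = 0; i < n; ++i)
        if (!obs(i, j)) Yaug(i, j) = mu(j) + A(i, j) + rnorm1() * sj;
    }
    // per-trait intercepts
    for (arma::uword j = 0; j < t; ++j)
      mu(j) = arma::mean(Yaug.col(j) - A.col(j))
              + rnorm1() * std::sqrt(Rv(j) / (double)n);
    // genetic values: one t x t solve per eigen-coordinate
    arma::mat Yt = Ut * (Yaug - arma::ones(n) * mu.t());
    arma::mat Rinv = arma::diagmat(1.0 / Rv);
    arma::mat Sinv;
    if (!arma::inv_sympd(Sinv, Sigma))
      Sinv = arma::inv_sympd(Sigma + arma::eye(t, t) * 1e-8);
    arma::mat Scatter = S0;
    for (arma::uword k = 0; k < pos.n_elem; ++k) {
      arma::uword i = pos(k);
      arma::mat P = Rinv + Sinv / d(i);
      arma::mat C = arma::inv_sympd(P);
      arma::vec m = C * (Rinv * Yt.row(i).t());
      arma::vec z(t);
      for (arma::uword j = 0; j < t; ++j) z(j) = rnorm1();
      arma::vec g = m + arma::chol(C, "lower") * z;
      Gamma.row(i) = g.t();
      Scatter += g * g.t() / d(i);
    }
    // genetic covariance: inverse-Wishart full conditional
    bool jit = false;
    Sigma = riwishart(nuS + npos, Scatter, jit);
    if (jit) ++n_jitter;
    // residual variances (R diagonal)
    A = U * Gamma;
    arma::mat E = Yaug - arma::ones(n) * mu.t() - A;
    for (arma::uword j = 0; j < t; ++j)
      Rv(j) = (nuR * s0R(j) + arma::dot(E.col(j), E.col(j)))
              / rchisq1(nuR + (double)n);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      sum_mu += mu; sum_R += Rv; sum_A += A;
      sum_pred += arma::ones(n) * mu.t() + A;
      sum_Sigma += Sigma;
      ch_R.row(kept) = Rv.t();
      ch_mu.row(kept) = mu.t();
      if (keep_sigma_chain)
        ch_Sigma.row(kept) = arma::vectorise(Sigma).t();
      double ll = 0;
      for (arma::uword j = 0; j < t; ++j) {
        arma::uvec oj = arma::find(obs.col(j) == 1);
        arma::vec ej = E.col(j);
        ll += -0.5 * (double)oj.n_elem * std::log(2.0 * M_PI * Rv(j))
              - 0.5 * arma::dot(ej.elem(oj), ej.elem(oj)) / Rv(j);
      }
      ch_ll(kept) = ll;
      ++kept;
    }
  }

  List chains = List::create(_["R"] = ch_R, _["mu"] = ch_mu, _["loglik"] = ch_ll);
  if (keep_sigma_chain) chains["Sigma"] = ch_Sigma;
  return List::create(
    _["mu_hat"] = sum_mu / kept,
    _["A_hat"] = sum_A / kept,
    _["pred_hat"] = sum_pred / kept,
    _["Sigma_hat"] = sum_Sigma / kept,
    _["R_hat"] = sum_R / kept,
    _["n_jitter"] = n_jitter,
    _["chains"] = chains);
}
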
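// Gibbs samplers for whole-genome regression (Bayesian ridge regression and
// BayesC-pi with spike-slab marker effects) and for a threshold GBLUP on the
// eigenbasis of the relationship kernel. Gaussian responses sample the
// residual variance; ordinal responses use the probit augmentation: a latent
// liability with residual variance fixed at 1, the first threshold fixed at
// 0, and the remaining thresholds sampled uniformly between the neighbouring
// order statistics. All randomness flows through R's RNG so chains are
// exactly reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rtruncnorm1(double mu, double lo, double hi) {
  // inverse-CDF sampler, adequate away from extreme tails
  double plo = R::pnorm(lo, mu, 1.0, 1, 0);
  double phi = R::pnorm(hi, mu, 1.0, 1, 0);
  if (phi - plo < 1e-12) {
    // numerically degenerate window: clamp to the nearer bound
    double mid = (lo > mu) ? lo : ((hi < mu) ? hi : mu);
    return std::min(std::max(mid, lo), hi);
  }
  double u = R::runif(plo, phi);
  double z = R::qnorm(u, mu, 1.0, 1, 0);
  if (z < lo) z = lo;
  if (z > hi) z = hi;
  return z;
}

static double rscaled_inv_chisq(double df, double sum_sq) {
  // draw from (sum_sq) / chisq(df)
  return sum_sq / R::rchisq(df);
}

// update liabilities and thresholds in place; categories in 0..C-1,
// thresholds tau (length C-1), tau[0] == 0 fixed
static void update_liabilities(const IntegerVector& cat, arma::vec& liab,
                               arma::vec& e, arma::vec& tau) {
  int n = cat.size();
  int C = tau.n_elem + 1;
  for (int i = 0; i < n; ++i) {
    double fitted = liab(i) - e(i);
    int c = cat[i];
    double lo = (c == 0) ? R_NegInf : tau(c - 1);
    double hi = (c == C - 1) ? R_PosInf : tau(c);
    liab(i) = rtruncnorm1(fitted, lo, hi);
    e(i) = liab(i) - fitted;
  }
  // thresholds 2..C-1 uniform between adjacent liability extremes
  for (int c = 1; c < C - 1; ++c) {
    double lo = tau(c - 1), hi = R_PosInf;
    bool any_lo = false, any_hi = false;
    for (int i = 0; i < n; ++i) {
      if (cat[i] == c && liab(i) > lo) { lo = std::max(lo, liab(i)); any_lo = true; }
      if (cat[i] == c + 1) { if (!any_hi || liab(i) < hi) hi = liab(i); any_hi = true; }
    }
    if (!any_lo) lo = tau(c - 1);
    if (!any_hi || hi <= lo) hi = lo + 1e-6;
    tau(c) = R::runif(lo, hi);
  }
}

// [[Rcpp::export]]
List brr_gibbs_cpp(NumericVector y_in, IntegerVector categories, bool ordinal,
                   arma::mat W, IntegerVector w_group, arma::mat Z,
                   int n_iter, int burn_in, int thin,
                   bool bayescpi,
                   double df0, double S0_m, double S0_e, double S0_b,
                   bool fix_var, double sigma2_m_fix, double sigma2_e_fix,
                   NumericVector tau_init, bool store_effects) {
  int n = W.n_rows, q = W.n_cols, m = Z.n_cols;
  arma::vec theta(q, arma::fill::zeros);
  arma::vec a(m, arma::fill::zeros);
  arma::vec delta(m, arma::fill::ones);
  double pi_incl = 0.5;
  double sigma2_e = fix_var ? sigma2_e_fix : 1.0;
  double sigma2_m = fix_var ? sigma2_m_fix : S0_m / df0 * 2.0;
  double sigma2_b = S0_b / df0 * 2.0;
  arma::vec tau(tau_init.begin(), tau_init.size());

  arma::vec liab(n);
  if (ordinal) {
    sigma2_e = 1.0;
    for (int i = 0; i < n; ++i) liab(i) = categories[i] - 1.0;
  } else {
    liab = arma::vec(y_in.begin(), n);
  }
  arma::vec e = liab; // residual given all effects zero
  arma::vec wtw(q), ztz(m);
  for (int j = 0; j < q; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));
  for (int j = 0; j < m; ++j) ztz(j) = arma::dot(Z.col(j), Z.col(j));

  int n_keep = 0;
  arma::vec a_mean(m, arma::fill::zeros), theta_mean(q, arma::fill::zeros);
  arma::vec incl_mean(m, arma::fill::zeros);
  arma::vec gebv_mean(n, arma::fill::zeros);
  std::vector<double> tr_s2m, tr_s2e, tr_s2b, tr_pi;
  std::vector<arma::vec> eff_draws;
  arma::vec tau_mean(tau.n_elem, arma::fill::zeros);

  for (int it = 1; it <= n_iter; ++it) {
    // location effects (flat prior group 0, block group 1)
    for (int j = 0; j < q; ++j) {
      if (wtw(j) <= 0) continue;
      e += W.col(j) * theta(j);
      double prior_prec = (w_group[j] == 0) ? 1e-10 : 1.0 / sigma2_b;
      double prec = wtw(j) / sigma2_e + prior_prec;
      double mean = (arma::dot(W.col(j), e) / sigma2_e) / prec;
      theta(j) = R::rnorm(mean, std::sqrt(1.0 / prec));
      e -= W.col(j) * theta(j);
    }
    // marker effects
    int m_in = 0;
    double ssq_a = 0.0;
    for (int j = 0; j < m; ++j) {
      double old = a(j);
      if (old != 0.0) e += Z.col(j) * old;
      double r = arma::dot(Z.col(j), e);
      double c = ztz(j);
      bool include = true;
      if (bayescpi) {
        double v1 = sigma2_e + c * sigma2_m;
        double logLR = 0.5 * std::log(sigma2_e / v1) +
          0.5 * r * r * sigma2_m / (sigma2_e * v1);
        double logodds = std::log(pi_incl / (1.0 - pi_incl)) + logLR;
        double pr = 1.0 / (1.0 + std::exp(-logodds));
        include = (R::runif(0.0, 1.0) < pr);
      }
      if (include) {
        double prec = c / sigma2_e + 1.0 / sigma2_m;
        double mean = (r / sigma2_e) / prec;
        a(j) = R::rnorm(mean, std::sqrt(1.0 / prec));
        e -= Z.col(j) * a(j);
        ++m_in;
        ssq_a += a(j) * a(j);
        delta(j) = 1.0;
      } else {
        a(j) = 0.0;
        delta(j) = 0.0;
      }
    }
    if (bayescpi) pi_incl = R::rbeta(1.0 + m_in, 1.0 + m - m_in);
    // variances
    if (!fix_var) {
      int m_eff = bayescpi ? m_in : m;
      double ss = bayescpi ? ssq_a : arma::dot(a, a);
      sigma2_m = rscaled_inv_chisq(df0 + m_eff, ss + df0 * S0_m);
      if (!ordinal)
        sigma2_e = rscaled_inv_chisq(df0 + n, arma::dot(e, e) + df0 * S0_e);
    }
    // block variance always sampled (location nuisance)
    double ssb = 0.0; int nb = 0;
    for (int j = 0; j < q; ++j) if (w_group[j] == 1) { ssb += theta(j) * theta(j); ++nb; }
    if (nb > 0) sigma2_b = rscaled_inv_chisq(df0 + nb, ssb + df0 * S0_b);
    // ordinal augmentation
    if (ordinal) update_liabilities(categories, liab, e, tau);

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++n_keep;
      a_mean += a;
      theta_mean += theta;
      incl_mean += delta;
      gebv_mean += Z * a;
      tr_s2m.push_back(sigma2_m);
      tr_s2e.push_back(sigma2_e);
      tr_s2b.push_back(sigma2_b);
      if (bayescpi) tr_pi.push_back(pi_incl);
      if (ordinal) tau_mean += tau;
      if (store_effects) eff_draws.push_back(a);
    }
  }
  a_mean /= n_keep; theta_mean /= n_keep; incl_mean /= n_keep;
  gebv_mean /= n_keep;
  if (n_keep > 0) tau_mean /= n_keep;
  NumericMatrix eff_out(store_effects ? n_keep : 0, store_effects ? m : 0);
  if (store_effects) {
    for (int i = 0; i < n_keep; ++i)
      for (int j = 0; j < m; ++j) eff_out(i, j) = eff_draws[i](j);
  }
  return List::create(
    _["a_mean"] = NumericVector(a_mean.begin(), a_mean.end()),
    _["theta_mean"] = NumericVector(theta_mean.begin(), theta_mean.end()),
    _["inclusion"] = NumericVector(incl_mean.begin(), incl_mean.end()),
    _["gebv_mean"] = NumericVector(gebv_mean.begin(), gebv_mean.end()),
    _["sigma2_m"] = wrap(tr_s2m), _["sigma2_e"] = wrap(tr_s2e),
    _["sigma2_b"] = wrap(tr_s2b), _["pi"] = wrap(tr_pi),
    _["tau_mean"] = NumericVector(tau_mean.begin(), tau_mean.end()),
    _["n_keep"] = n_keep, _["effects"] = eff_out);
}

// [[Rcpp::export]]
List tgblup_gibbs_cpp(IntegerVector categories, arma::mat U, arma::vec d,
                      arma::mat W, IntegerVector w_group,
                      int n_iter, int burn_in, int thin,
                      double df0, double S0_a, double S0_b,
                      NumericVector tau_init) {
  int n = U.n_rows, r = U.n_cols, q = W.n_cols;
  arma::vec theta(q, arma::fill::zeros), gam(r, arma::fill::zeros);
  double sigma2_a = S0_a / df0 * 2.0, sigma2_b = S0_b / df0 * 2.0;
  arma::vec tau(tau_init.begin(), tau_init.size());
  arma::vec liab(n);
  for (int i = 0; i < n; ++i) liab(i) = categories[i] - 1.0;
  arma::vec e = liab;
  arma::vec wtw(q);
  for (int j = 0; j < q; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));

  int n_keep = 0;
  arma::vec a_sum(n, arma::fill::zeros);
  std::vector<double> tr_s2a;
  arma::vec tau_mean(tau.n_elem, arma::fill::zeros);

  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < q; ++j) {
      if (wtw(j) <= 0) continue;
      e += W.col(j) * theta(j);
      double prior_prec = (w_group[j] == 0) ? 1e-10 : 1.0 / sigma2_b;
      double prec = wtw(j) + prior_prec; // residual variance 1
      double mean = arma::dot(W.col(j), e) / prec;
      theta(j) = R::rnorm(mean, std::sqrt(1.0 / prec));
      e -= W.col(j) * theta(j);
    }
    // additive effects on the eigenbasis: posterior is diagonal because
    // U'U = I and the liability residual variance is 1
    arma::vec ctx = e + U * gam;
    arma::vec v = U.t() * ctx;
    for (int j = 0; j < r; ++j) {
      double prec = 1.0 / (sigma2_a * d(j)) + 1.0;
      double mean = v(j) / prec;
      gam(j) = R::rnorm(mean, std::sqrt(1.0 / prec));
    }
    e = ctx - U * gam;
    double ss = 0.0;
    for (int j = 0; j < r; ++j) ss += gam(j) * gam(j) / d(j);
    sigma2_a = rscaled_inv_chisq(df0 + r, ss + df0 * S0_a);
    double ssb = 0.0; int nb = 0;
    for (int j = 0; j < q; ++j) if (w_group[j] == 1) { ssb += theta(j) * theta(j); ++nb; }
    if (nb > 0) sigma2_b = rscaled_inv_chisq(df0 + nb, ssb + df0 * S0_b);
    update_liabilities(categories, liab, e, tau);

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++n_keep;
      a_sum += U * gam;
      tr_s2a.push_back(sigma2_a);
      tau_mean += tau;
    }
  }
  a_sum /= n_keep;
  tau_mean /= n_keep;
  return List::create(
    _["a_mean"] = NumericVector(a_sum.begin(), a_sum.end()),
    _["sigma2_a"] = wrap(tr_s2a),
    _["tau_mean"] = NumericVector(tau_mean.begin(), tau_mean.end()),
    _["n_keep"] = n_keep);
}
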
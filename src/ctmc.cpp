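// Core numerical kernels: Felsenstein pruning for k-state CTMCs on trees,
// and the MCMC sweep for the phylogenetic logistic regression.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Transition probability matrices P(t) = exp(Q t) for a set of branch
// lengths, via eigendecomposition of Q (computed once), with a Pade
// (arma::expmat) fallback when Q is defective or the eigenbasis is
// ill-conditioned.
static bool eig_setup(const arma::mat& Q, arma::cx_vec& eval,
                      arma::cx_mat& evec, arma::cx_mat& evec_inv) {
  if (!arma::eig_gen(eval, evec, Q)) return false;
  arma::cx_mat inv;
  if (!arma::inv(inv, evec)) return false;
  // reject near-defective eigenbases
  if (arma::norm(evec * inv - arma::eye<arma::cx_mat>(Q.n_rows, Q.n_rows),
                 "fro") > 1e-8) return false;
  evec_inv = inv;
  return true;
}

static arma::mat pmat(const arma::mat& Q, double t, bool have_eig,
                      const arma::cx_vec& eval, const arma::cx_mat& evec,
                      const arma::cx_mat& evec_inv) {
  arma::mat P;
  if (have_eig) {
    arma::cx_mat M = evec * arma::diagmat(arma::exp(eval * t)) * evec_inv;
    P = arma::real(M);
  } else {
    P = arma::expmat(Q * t);
  }
  P.elem(arma::find(P < 0)).zeros();
  return P;
}

//' @noRd
// [[Rcpp::export(name = ".ctmc_loglik_cpp")]]
double ctmc_loglik_cpp(const arma::imat& edge, const arma::vec& elen,
                       int n_tips, int n_nodes, const arma::mat& tip_partials,
                       const arma::mat& Q, const arma::vec& root_prior,
                       int root) {
  const int k = Q.n_rows;
  arma::cx_vec eval; arma::cx_mat evec, evec_inv;
  const bool have_eig = eig_setup(Q, eval, evec, evec_inv);

  arma::mat L(k, n_nodes, arma::fill::ones);
  L.cols(0, n_tips - 1) = tip_partials;
  double logscale = 0.0;

  // edges in postorder: child partial is complete before its edge is used
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    arma::mat P = pmat(Q, elen(e), have_eig, eval, evec, evec_inv);
    arma::vec v = P * L.col(ch);
    const double s = arma::accu(v);
    if (!(s > 0) || !std::isfinite(s)) return -std::numeric_limits<double>::infinity();
    logscale += std::log(s);
    L.col(par) %= (v / s);
  }
  const double lik = arma::dot(root_prior, L.col(root - 1));
  if (!(lik > 0)) return -std::numeric_limits<double>::infinity();
  return std::log(lik) + logscale;
}

//' @noRd
// [[Rcpp::export(name = ".pglmm_mcmc_cpp")]]
List pglmm_mcmc_cpp(const arma::vec& y, const arma::mat& X,
                    const arma::mat& Cinv, int n_iter, int burn_in, int thin,
                    double prior_shape, double prior_scale,
                    double beta_prior_var, arma::vec beta,
                    arma::vec prop_sd) {
  const int n = y.n_elem, p = X.n_cols;
  arma::vec u(n, arma::fill::zeros);
  double sigma2 = 1.0;
  arma::vec eta = X * beta + u;               // latent linear predictor
  arma::vec s = Cinv * u;                     // maintained incrementally
  const arma::vec cdiag = Cinv.diag();

  auto site_ll = [&](double et, double yi) {
    // Bernoulli-logit log-likelihood, overflow-safe
    return yi * et - (et > 30 ? et : std::log1p(std::exp(et)));
  };
  auto full_ll = [&](const arma::vec& e) {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) ll += site_ll(e(i), y(i));
    return ll;
  };

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat beta_out(n_keep, p);
  arma::vec sigma2_out(n_keep);
  arma::vec u_mean(n, arma::fill::zeros);
  arma::vec acc(p, arma::fill::zeros), tries(p, arma::fill::zeros);
  double u_acc = 0.0, u_tries = 0.0;
  int kept = 0;

  double cur_ll = full_ll(eta);
  for (int it = 0; it < n_iter; ++it) {
    // fixed effects: one-at-a-time random-walk Metropolis
    for (int j = 0; j < p; ++j) {
      const double bj_new = beta(j) + R::rnorm(0.0, prop_sd(j));
      arma::vec eta_new = eta + X.col(j) * (bj_new - beta(j));
      const double ll_new = full_ll(eta_new);
      const double lp = -0.5 * (bj_new * bj_new - beta(j) * beta(j)) / beta_prior_var;
      tries(j) += 1;
      if (std::log(R::runif(0.0, 1.0)) < ll_new - cur_ll + lp) {
        beta(j) = bj_new; eta = eta_new; cur_ll = ll_new; acc(j) += 1;
      }
    }
    // species random effects: independence proposal from the conditional
    // prior N(m_i, v_i); acceptance ratio reduces to the site likelihood
    for (int i = 0; i < n; ++i) {
      const double prec_i = cdiag(i) / sigma2;
      const double m_i = -((s(i) - cdiag(i) * u(i)) / sigma2) / prec_i;
      const double ui_new = R::rnorm(m_i, std::sqrt(1.0 / prec_i));
      const double eta_new = eta(i) - u(i) + ui_new;
      const double d = site_ll(eta_new, y(i)) - site_ll(eta(i), y(i));
      u_tries += 1;
      if (std::log(R::runif(0.0, 1.0)) < d) {
        s += Cinv.col(i) * (ui_new - u(i));
        cur_ll += d;
        eta(i) = eta_new;
        u(i) = ui_new;
        u_acc += 1;
      }
    }
    // variance: conjugate inverse-gamma update
    const double quad = arma::dot(u, s);
    sigma2 = 1.0 / R::rgamma(prior_shape + 0.5 * n,
                             1.0 / (prior_scale + 0.5 * quad));

    // adapt proposal scales during burn-in only
    if (it < burn_in && (it + 1) % 50 == 0) {
      for (int j = 0; j < p; ++j) {
        const double r = acc(j) / std::max(1.0, tries(j));
        prop_sd(j) *= std::exp(0.5 * (r - 0.44));
        acc(j) = 0; tries(j) = 0;
      }
    }
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      beta_out.row(kept) = beta.t();
      sigma2_out(kept) = sigma2;
      u_mean += u;
      ++kept;
    }
  }
  if (kept > 0) u_mean /= kept;
  return List::create(_["beta"] = beta_out, _["sigma2"] = sigma2_out,
                      _["u_mean"] = u_mean,
                      _["accept_beta"] = acc / arma::clamp(tries, 1.0, arma::datum::inf),
                      _["accept_u"] = u_acc / std::max(1.0, u_tries),
                      _["prop_sd"] = prop_sd);
}
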
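// Gibbs sampler (with a Metropolis-Hastings step for the joint
// additive/dominance update) for BayesA and BayesAD marker-effect models.
//
// Model: y = X b + Wa alpha + Wb beta + e
//   alpha_j | sigma_aj2        ~ N(0, sigma_aj2)
//   sigma_aj2                  ~ scaled-inv-chi2(nu_alpha, s_alpha2)
//   beta_j  | alpha_j          ~ N(mu_beta, sD^2 * sigma_aj2)   (BayesAD)
//   b, sigma_e2                ~ flat
//
// The (alpha_j, beta_j) pair is updated by an independence MH proposal:
// alpha_j* from the BayesA-style Gaussian full conditional computed on the
// residual with SNP j fully removed, beta_j* from its conditional prior.
// The prior and proposal terms for alpha cancel up to the residual
// likelihoods, so the acceptance ratio involves only residual sums of
// squares (all expressible with per-SNP dot products).

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List bayes_chain_cpp(const arma::vec& y,
                     const arma::mat& X,
                     const arma::mat& Wa,
                     const arma::mat& Wb,
                     const bool dominance,
                     const double nu_alpha,
                     const double s_alpha2,
                     const double s_D,
                     const double mu_beta,
                     const int n_iter,
                     const int burn_in,
                     const int thin,
                     const double fixed_sigma_e2, // <= 0: sample it
                     const bool store_draws) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int m = Wa.n_cols;
  const double sD2 = s_D * s_D;

  // precomputations
  arma::mat XtX = X.t() * X;
  arma::mat Rx = arma::chol(XtX); // upper
  arma::vec wa2(m), wb2(m), wab(m);
  for (int j = 0; j < m; ++j) {
    wa2(j) = arma::dot(Wa.col(j), Wa.col(j));
    if (dominance) {
      wb2(j) = arma::dot(Wb.col(j), Wb.col(j));
      wab(j) = arma::dot(Wa.col(j), Wb.col(j));
    }
  }

  // state
  arma::vec b(p, arma::fill::zeros);
  arma::vec alpha(m, arma::fill::zeros);
  arma::vec beta(m, arma::fill::zeros);
  arma::vec sa2(m);
  sa2.fill(s_alpha2 * nu_alpha / std::max(nu_alpha - 2.0, 0.5));
  double sigma_e2 = (fixed_sigma_e2 > 0.0) ? fixed_sigma_e2 : arma::var(y);
  arma::vec r = y; // residual at b=0, alpha=0, beta=0

  const int n_keep = (n_iter - burn_in) / thin;
  arma::vec alpha_mean(m, arma::fill::zeros), alpha_m2(m, arma::fill::zeros);
  arma::vec beta_mean(m, arma::fill::zeros), beta_m2(m, arma::fill::zeros);
  arma::vec sa2_mean(m, arma::fill::zeros);
  arma::vec b_mean(p, arma::fill::zeros);
  arma::vec sigma_e2_draws(n_keep, arma::fill::zeros);
  arma::mat alpha_draws, beta_draws;
  if (store_draws) {
    alpha_draws.set_size(n_keep, m);
    if (dominance) beta_draws.set_size(n_keep, m);
  }

  long long mh_accept = 0, mh_total = 0;
  int kept = 0;
  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects: b | rest ~ N((X'X)^-1 X'(r + Xb), sigma_e2 (X'X)^-1)
    arma::vec rb = r + X * b;
    arma::vec bhat = arma::solve(XtX, X.t() * rb);
    arma::vec z(p);
    for (int k = 0; k < p; ++k) z(k) = R::rnorm(0.0, 1.0);
    arma::vec bnew = bhat + std::sqrt(sigma_e2) * arma::solve(arma::trimatu(Rx), z);
    r = rb - X * bnew;
    b = bnew;

    // --- per-SNP updates
    for (int j = 0; j < m; ++j) {
      const double aj = alpha(j);
      const double bj = beta(j);
      // sigma_aj2 | alpha_j (, beta_j)
      double df, ssq;
      if (dominance) {
        df = nu_alpha + 2.0;
        ssq = nu_alpha * s_alpha2 + aj * aj + (bj - mu_beta) * (bj - mu_beta) / sD2;
      } else {
        df = nu_alpha + 1.0;
        ssq = nu_alpha * s_alpha2 + aj * aj;
      }
      sa2(j) = ssq / R::rchisq(df);

      // residual with SNP j removed: dot products only
      const double ra = arma::dot(Wa.col(j), r) + wa2(j) * aj +
        (dominance ? wab(j) * bj : 0.0);
      const double cinv = 1.0 / (wa2(j) + sigma_e2 / sa2(j));
      const double amean = ra * cinv;
      const double avar = sigma_e2 * cinv;

      if (!dominance) {
        const double anew = amean + std::sqrt(avar) * R::rnorm(0.0, 1.0);
        r += Wa.col(j) * (aj - anew);
        alpha(j) = anew;
      } else {
        const double rbdot = arma::dot(Wb.col(j), r) + wab(j) * aj + wb2(j) * bj;
        const double astar = amean + std::sqrt(avar) * R::rnorm(0.0, 1.0);
        const double bstar = mu_beta + std::sqrt(sD2 * sa2(j)) * R::rnorm(0.0, 1.0);
        // log acceptance: residual likelihoods only (priors/proposals cancel)
        const double delta =
          (-2.0 * bstar * rbdot + bstar * bstar * wb2(j) + 2.0 * astar * bstar * wab(j)) -
          (-2.0 * bj * rbdot + bj * bj * wb2(j) + 2.0 * aj * bj * wab(j));
        const double logA = -delta / (2.0 * sigma_e2);
        ++mh_total;
        if (std::log(R::runif(0.0, 1.0)) < logA) {
          ++mh_accept;
          r += Wa.col(j) * (aj - astar) + Wb.col(j) * (bj - bstar);
          alpha(j) = astar;
          beta(j) = bstar;
        }
      }
    }

    // --- residual variance (flat prior): scaled-inv-chi2(n - 2, SSR/(n - 2))
    if (fixed_sigma_e2 <= 0.0) {
      const double ssr = arma::dot(r, r);
      sigma_e2 = ssr / R::rchisq((double)n - 2.0);
      if (!std::isfinite(sigma_e2) || sigma_e2 <= 0.0) {
        stop("residual variance became non-finite at iteration %d", it + 1);
      }
    }

    // --- bookkeeping
    if (it >= burn_in && ((it - burn_in) % thin == 0) && kept < n_keep) {
      alpha_mean += alpha; alpha_m2 += arma::square(alpha);
      beta_mean += beta; beta_m2 += arma::square(beta);
      sa2_mean += sa2;
      b_mean += b;
      sigma_e2_draws(kept) = sigma_e2;
      if (store_draws) {
        alpha_draws.row(kept) = alpha.t();
        if (dominance) beta_draws.row(kept) = beta.t();
      }
      ++kept;
    }
  }

  const double K = std::max(kept, 1);
  alpha_mean /= K; beta_mean /= K; sa2_mean /= K; b_mean /= K;
  arma::vec alpha_sd = arma::sqrt(arma::clamp(alpha_m2 / K - arma::square(alpha_mean), 0.0, arma::datum::inf));
  arma::vec beta_sd = arma::sqrt(arma::clamp(beta_m2 / K - arma::square(beta_mean), 0.0, arma::datum::inf));

  List out = List::create(
    _["alpha_mean"] = alpha_mean,
    _["alpha_sd"] = alpha_sd,
    _["beta_mean"] = beta_mean,
    _["beta_sd"] = beta_sd,
    _["sigma_alpha2_mean"] = sa2_mean,
    _["b_mean"] = b_mean,
    _["sigma_e2_draws"] = sigma_e2_draws,
    _["n_kept"] = kept,
    _["acceptance_rate"] = dominance && mh_total > 0
      ? (double)mh_accept / (double)mh_total : NA_REAL
  );
  if (store_draws) {
    out["alpha_draws"] = alpha_draws;
    if (dominance) out["beta_draws"] = beta_draws;
  }
  return out;
}
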
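#' Hyperparameters for BayesA / BayesAD
#'
#' Additive marker effects have per-SNP variances with a scaled inverse
#' chi-square prior (`nu_alpha` degrees of freedom, scale `s_alpha2`),
#' giving a Student-t marginal; dominance effects are conditionally
#' Gaussian, `beta_j | alpha_j ~ N(mu_beta, s_D^2 sigma_alpha_j^2)`.
#' The fixed effects and the residual variance carry flat priors.
#'
#' @param nu_alpha prior degrees of freedom (> 2, so the prior marker
#'   variance `s_alpha2 * nu_alpha / (nu_alpha - 2)` is finite).  Default
#'   4.2, the usual heavy-tailed BayesA convention.
#' @param s_alpha2 prior scale; see [derive_scale()] for a data-driven
#'   choice.
#' @param s_D dominance scale multiplier (> 0), default 0.5.
#' @param mu_beta dominance prior location, default 0.
#' @param n_iterations,burn_in,thinning chain controls.
#' @param seed integer RNG seed.
#' @return list of class `bayes_hyper`.
#' @export
bayes_hyper <- function(nu_alpha = 4.2, s_alpha2 = NULL, s_D = 0.5,
                        mu_beta = 0, n_iterations = 20000L, burn_in = 5000L,
                        thinning = 10L, seed = 1L) {
  if (nu_alpha <= 2) stop("nu_alpha must exceed 2 for a finite prior variance")
  if (!is.null(s_alpha2) && s_alpha2 <= 0) stop("s_alpha2 must be positive")
  if (s_D <= 0) stop("s_D must be positive")
  if (burn_in >= n_iterations) stop("burn_in must be below n_iterations")
  if (thinning < 1) stop("thinning must be >= 1")
  structure(
    list(nu_alpha = nu_alpha, s_alpha2 = s_alpha2, s_D = s_D,
         mu_beta = mu_beta, n_iterations = as.integer(n_iterations),
         burn_in = as.integer(burn_in), thinning = as.integer(thinning),
         seed = as.integer(seed)),
    class = "bayes_hyper"
  )
}

#' Marker design matrices for BayesA / BayesAD
#'
#' Additive coding `Wa` is the raw dosage (0/1/2 copies of allele2),
#' dominance coding `Wb` the heterozygote indicator (0/1/0); both are
#' column-centred internally and the centring constants stored so that
#' predictions for new individuals are intercept-consistent.  Missing
#' dosages are filled with the column mean before centring.
#'
#' @param geno a [genotype_matrix()].
#' @param centers optional list with `center_a`, `center_d` from a previous
#'   (training) call, applied instead of the column means of `geno`.
#' @return list of class `marker_designs`: `Wa`, `Wb` (centred), and
#'   `center_a`, `center_d`.
#' @export
build_designs <- function(geno, centers = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dos <- geno$dosages
  n_missing <- sum(is.na(dos))
  Wa <- dos * 1.0
  Wb <- (dos == 1L) * 1.0
  if (n_missing > 0) {
    warning(sprintf("%d missing dosages filled with column means", n_missing))
    cm_a <- colMeans(Wa, na.rm = TRUE)
    cm_b <- colMeans(Wb, na.rm = TRUE)
    na_idx <- which(is.na(dos))
    Wa[na_idx] <- rep(cm_a, each = nrow(dos))[na_idx]
    Wb[na_idx] <- rep(cm_b, each = nrow(dos))[na_idx]
  }
  if (is.null(centers)) {
    center_a <- colMeans(Wa)
    center_d <- colMeans(Wb)
  } else {
    center_a <- centers$center_a
    center_d <- centers$center_d
  }
  structure(
    list(Wa = sweep(Wa, 2L, center_a, "-"),
         Wb = sweep(Wb, 2L, center_d, "-"),
         center_a = center_a, center_d = center_d,
         snp_id = geno$snp_meta$snp_id),
    class = "marker_designs"
  )
}

#' Data-driven prior scale for the marker-variance prior
#'
#' Chooses `s_alpha2` so that the prior additive genetic variance implied
#' by the marker model matches a target fraction of the phenotypic
#' variance:
#' `s_alpha2 = h2_target * var(y) * (nu_alpha - 2) / (nu_alpha * sum(2 p_i q_i))`,
#' inverting `var(alpha_j) = s_alpha2 * nu_alpha / (nu_alpha - 2)` summed
#' over loci with heterozygosity weights `2 p_i q_i`.
#'
#' @param h2_target assumed additive heritability in `(0, 1)`.
#' @param var_y phenotypic variance.
#' @param geno a [genotype_matrix()] (for allele frequencies), or
#'   alternatively pass `sum2pq` directly.
#' @param nu_alpha prior degrees of freedom (> 2).
#' @param sum2pq optional precomputed `sum(2 p_i q_i)`.
#' @return scalar `s_alpha2`.
#' @export
derive_scale <- function(h2_target, var_y, geno = NULL, nu_alpha = 4.2,
                         sum2pq = NULL) {
  stopifnot(h2_target > 0, h2_target < 1, nu_alpha > 2, var_y > 0)
  if (is.null(sum2pq)) {
    p <- allele_frequencies(geno)
    sum2pq <- sum(2 * p * (1 - p))
  }
  if (sum2pq <= 0) stop("sum(2pq) is zero: genotypes are degenerate")
  h2_target * var_y * (nu_alpha - 2) / (nu_alpha * sum2pq)
}

#' Run a BayesA or BayesAD Markov chain
#'
#' Gibbs sampling with, for BayesAD, a Metropolis-Hastings step updating
#' each SNP's (additive, dominance) effect pair jointly: the proposal draws
#' the additive effect from its BayesA-style Gaussian full conditional and
#' the dominance effect from its conditional prior, so the acceptance
#' ratio reduces to a ratio of residual likelihoods.  Chains are seeded and
#' reproducible.
#'
#' @param design a [trait_design()] (phenotype and fixed-effects matrix).
#' @param designs a [build_designs()] object with the centred `Wa`, `Wb`.
#' @param hyper a [bayes_hyper()]; when `hyper$s_alpha2` is `NULL` it is
#'   derived via [derive_scale()] with a target of 0.5.
#' @param model `"bayesA"` (dominance effects fixed at zero) or
#'   `"bayesAD"`.
#' @param fixed_sigma_e2 optionally fix the residual variance instead of
#'   sampling it (used e.g. for prior-predictive checks).
#' @param store_draws keep the thinned per-SNP effect draws (memory grows
#'   with `m`); posterior means/SDs are always returned.
#' @return list of class `marker_effect_samples`: posterior means/SDs of
#'   `alpha` and `beta`, mean per-SNP variances, fixed-effect means,
#'   `sigma_e2_draws`, `acceptance_rate`, the model label, hyperparameters
#'   and centring constants.
#' @export
run_chain <- function(design, designs, hyper = bayes_hyper(),
                      model = c("bayesAD", "bayesA"),
                      fixed_sigma_e2 = NULL, store_draws = FALSE) {
  stopifnot(inherits(design, "trait_design"), inherits(designs, "marker_designs"))
  model <- match.arg(model)
  if (nrow(designs$Wa) != length(design$y)) stop("design/genotype dimension mismatch")
  s_alpha2 <- hyper$s_alpha2
  if (is.null(s_alpha2)) {
    # prior belief: half the phenotypic variance is additive-genetic
    sum2pq_eff <- sum(apply(designs$Wa, 2, var)) # var of dosage ~ 2pq under HWE
    s_alpha2 <- derive_scale(0.5, var(design$y), nu_alpha = hyper$nu_alpha,
                             sum2pq = sum2pq_eff)
  }
  set.seed(hyper$seed)
  res <- bayes_chain_cpp(
    design$y, design$X, designs$Wa, designs$Wb,
    dominance = (model == "bayesAD"),
    nu_alpha = hyper$nu_alpha, s_alpha2 = s_alpha2,
    s_D = hyper$s_D, mu_beta = hyper$mu_beta,
    n_iter = hyper$n_iterations, burn_in = hyper$burn_in,
    thin = hyper$thinning,
    fixed_sigma_e2 = if (is.null(fixed_sigma_e2)) -1 else fixed_sigma_e2,
    store_draws = store_draws
  )
  for (nm in c("alpha_mean", "alpha_sd", "beta_mean", "beta_sd",
               "sigma_alpha2_mean", "b_mean", "sigma_e2_draws")) {
    res[[nm]] <- as.numeric(res[[nm]])
  }
  if (model == "bayesAD" && !is.na(res$acceptance_rate) &&
      res$acceptance_rate < 0.01) {
    warning(sprintf("MH acceptance rate very low (%.3f)", res$acceptance_rate))
  }
  structure(
    c(res,
      list(model = model, hyper = hyper, s_alpha2_used = s_alpha2,
           center_a = designs$center_a, center_d = designs$center_d,
           snp_id = designs$snp_id)),
    class = "marker_effect_samples"
  )
}

#' @export
print.marker_effect_samples <- function(x, ...) {
  cat(sprintf("%s chain: %d retained draws, %d SNPs", x$model, x$n_kept,
              length(x$alpha_mean)))
  if (!is.na(x$acceptance_rate)) {
    cat(sprintf(", MH acceptance %.2f", x$acceptance_rate))
  }
  cat(sprintf(", posterior mean sigma_e2 = %.4g\n", mean(x$sigma_e2_draws)))
  invisible(x)
}

#' Predict genetic values from posterior mean marker effects
#'
#' Breeding values are `Wa %*% mean(alpha)`; total genetic values add the
#' dominance part `Wb %*% mean(beta)`.  The designs must be centred with
#' the training centring constants (pass `centers` to [build_designs()]
#' for validation individuals).
#'
#' @param samples a `marker_effect_samples` object.
#' @param designs a [build_designs()] object for the individuals to
#'   predict.
#' @return list with `breeding` and `total` numeric vectors.
#' @export
predict_genetic_values <- function(samples, designs) {
  stopifnot(inherits(samples, "marker_effect_samples"),
            inherits(designs, "marker_designs"))
  if (ncol(designs$Wa) != length(samples$alpha_mean)) {
    stop("number of SNPs differs between samples and designs")
  }
  breeding <- drop(designs$Wa %*% samples$alpha_mean)
  total <- breeding + drop(designs$Wb %*% samples$beta_mean)
  list(breeding = breeding, total = total)
}

#' Posterior summary table
#'
#' @param samples a `marker_effect_samples` object.
#' @return data frame: snp_id, posterior mean/SD of additive and dominance
#'   effects.
#' @export
bayes_summary <- function(samples) {
  data.frame(
    snp_id = samples$snp_id,
    alpha_mean = samples$alpha_mean, alpha_sd = samples$alpha_sd,
    beta_mean = samples$beta_mean, beta_sd = samples$beta_sd,
    stringsAsFactors = FALSE
  )
}
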
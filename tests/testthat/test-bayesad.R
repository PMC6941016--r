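test_that("marker design codings follow the 0/1/2 and 0/1/0 conventions", {
  g <- toy_geno(cbind(c(0L, 1L, 2L), c(0L, 0L, 2L)))
  d <- build_designs(g)
  # recover the raw codings by undoing the centring
  expect_equal(sweep(d$Wa, 2, d$center_a, "+"), cbind(c(0, 1, 2), c(0, 0, 2)))
  expect_equal(sweep(d$Wb, 2, d$center_d, "+"), cbind(c(0, 1, 0), c(0, 0, 0)))
  expect_lt(max(abs(colMeans(d$Wa))), 1e-12)
  expect_lt(max(abs(colMeans(d$Wb))), 1e-12)
  # missing dosages: column-mean fill with a warning
  g$dosages[2, 1] <- NA
  expect_warning(d2 <- build_designs(g), "missing")
  expect_lt(max(abs(colMeans(d2$Wa))), 1e-12)
})

test_that("derive_scale inverts the prior-variance identity", {
  ds <- quick_dataset(n = 100, m = 60, seed = 51)
  g <- ds$genotypes
  p <- allele_frequencies(g)
  s2pq <- sum(2 * p * (1 - p))
  vy <- var(ds$phenotypes$trait)
  nu <- 4.2
  s <- derive_scale(0.35, vy, g, nu_alpha = nu)
  # plug back: prior marker variance times sum(2pq) recovers h2 * var(y)
  expect_equal(s * nu / (nu - 2) * s2pq, 0.35 * vy, tolerance = 1e-12)
  expect_equal(derive_scale(0.35, 2 * vy, g, nu_alpha = nu), 2 * s,
               tolerance = 1e-12)
  # nu -> infinity limit
  expect_equal(derive_scale(0.35, vy, g, nu_alpha = 1e9),
               0.35 * vy / s2pq, tolerance = 1e-6)
})

test_that("chains are reproducible from the seed", {
  ds <- quick_dataset(n = 80, m = 60, seed = 52)
  d <- build_designs(ds$genotypes)
  hy <- bayes_hyper(n_iterations = 400, burn_in = 100, thinning = 2, seed = 9)
  c1 <- run_chain(ds$design, d, hy, model = "bayesAD")
  c2 <- run_chain(ds$design, d, hy, model = "bayesAD")
  expect_identical(c1$alpha_mean, c2$alpha_mean)
  expect_identical(c1$beta_mean, c2$beta_mean)
  expect_identical(c1$sigma_e2_draws, c2$sigma_e2_draws)
  hy2 <- bayes_hyper(n_iterations = 400, burn_in = 100, thinning = 2, seed = 10)
  c3 <- run_chain(ds$design, d, hy2, model = "bayesAD")
  expect_false(identical(c1$alpha_mean, c3$alpha_mean))
})

test_that("null data are calibrated: no spurious effects, honest sigma_e2", {
  # records must clearly outnumber markers for the residual variance to be
  # identifiable against the marker fit under an informative prior
  set.seed(53)
  n <- 600
  m <- 150
  g <- simulate_genotypes(sim_config(n_individuals = n, n_snps = m, seed = 53))
  y <- rnorm(n, 0, 2)
  des <- trait_design(y, NULL)
  d <- build_designs(g)
  ch <- run_chain(des, d, bayes_hyper(n_iterations = 1500, burn_in = 500,
                                      thinning = 2, seed = 53),
                  model = "bayesAD")
  # compare against the realized noise variance (y is pure residual here)
  expect_lt(abs(mean(ch$sigma_e2_draws) - var(y)) / var(y), 0.10)
  z_a <- abs(ch$alpha_mean) / pmax(ch$alpha_sd, 1e-12)
  z_d <- abs(ch$beta_mean) / pmax(ch$beta_sd, 1e-12)
  expect_true(all(z_a < 3))
  expect_true(all(z_d < 3))
})

test_that("a large additive QTL is recovered with the right sign", {
  hits <- vapply(1:20, function(s) {
    set.seed(7000 + s)
    n <- 250
    m <- 400
    g <- simulate_genotypes(sim_config(n_individuals = n, n_snps = m,
                                       seed = 7000 + s))
    wa <- g$dosages[, 200]
    eff <- sqrt(0.30 / 0.70 * 1 / var(wa)) # QTL explains ~30% of variance
    y <- wa * eff + rnorm(n)
    des <- trait_design(y, NULL)
    d <- build_designs(g)
    ch <- run_chain(des, d, bayes_hyper(n_iterations = 800, burn_in = 300,
                                        thinning = 2, seed = s),
                    model = "bayesA")
    which.max(abs(ch$alpha_mean)) == 200 && ch$alpha_mean[200] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("near-Gaussian BayesA matches GBLUP predictions", {
  ds <- quick_dataset(n = 300, m = 600, seed = 55)
  g <- ds$genotypes
  des <- ds$design
  vy <- var(corrected_phenotypes(des))
  nu <- 1e6
  s_alpha2 <- derive_scale(0.5, vy, g, nu_alpha = nu)
  hy <- bayes_hyper(nu_alpha = nu, s_alpha2 = s_alpha2, seed = 55,
                    n_iterations = 3000, burn_in = 1000, thinning = 2)
  # residual variance fixed so both models shrink identically
  sigma_e2 <- 0.5 * vy
  ch <- run_chain(des, build_designs(g), hy, model = "bayesA",
                  fixed_sigma_e2 = sigma_e2)
  pred_bayes <- predict_genetic_values(ch, build_designs(g))$breeding
  G <- stabilize(build_G(g), 1e-8)
  vc <- list(sigma_a2 = s_alpha2 * G$scale_denominator, sigma_d2 = NA_real_,
             sigma_e2 = sigma_e2)
  sol <- blup_solve(des, list(G), vc)
  expect_gt(cor(pred_bayes, sol$a_hat), 0.99)
})

test_that("BayesAD with a tiny dominance scale reproduces BayesA", {
  ds <- quick_dataset(n = 150, m = 200, seed = 56)
  d <- build_designs(ds$genotypes)
  hyA <- bayes_hyper(n_iterations = 2000, burn_in = 500, thinning = 2, seed = 3)
  hyAD <- bayes_hyper(n_iterations = 2000, burn_in = 500, thinning = 2, seed = 3,
                      s_D = 1e-4, mu_beta = 0)
  chA <- run_chain(ds$design, d, hyA, model = "bayesA")
  chAD <- run_chain(ds$design, d, hyAD, model = "bayesAD")
  expect_lt(max(abs(chAD$beta_mean)), 1e-2)
  expect_gt(cor(chA$alpha_mean, chAD$alpha_mean), 0.95)
})

test_that("with one SNP and fixed variances the posterior matches conjugate theory", {
  set.seed(57)
  n <- 120
  wa <- rbinom(n, 2, 0.4)
  alpha_true <- 0.8
  sigma_e2 <- 1.5
  y <- wa * alpha_true + rnorm(n, 0, sqrt(sigma_e2))
  g <- toy_geno(matrix(as.integer(wa), n, 1))
  des <- trait_design(y, NULL)
  d <- build_designs(g)
  # huge nu pins sigma_alpha2 at s_alpha2: effectively a fixed-variance model
  sa2 <- 0.5
  hy <- bayes_hyper(nu_alpha = 1e8, s_alpha2 = sa2, seed = 57,
                    n_iterations = 6000, burn_in = 1000, thinning = 1)
  ch <- run_chain(des, d, hy, model = "bayesA", fixed_sigma_e2 = sigma_e2,
                  store_draws = TRUE)
  wc <- d$Wa[, 1]
  # conjugate posterior given the centred design and known variances;
  # the intercept is profiled out by centring
  yc <- y - mean(y)
  post_var <- 1 / (sum(wc^2) / sigma_e2 + 1 / sa2)
  post_mean <- post_var * sum(wc * yc) / sigma_e2
  expect_equal(ch$alpha_mean[1], post_mean, tolerance = 0.05)
  expect_equal(ch$alpha_sd[1]^2, post_var, tolerance = 0.2)
})

test_that("uninformative data reproduce the scaled-t prior marginal", {
  set.seed(58)
  n <- 60
  m <- 120
  g <- simulate_genotypes(sim_config(n_individuals = n, n_snps = m, seed = 58))
  y <- rnorm(n)
  des <- trait_design(y, NULL)
  d <- build_designs(g)
  nu <- 4.2
  sa2 <- 0.8
  hy <- bayes_hyper(nu_alpha = nu, s_alpha2 = sa2, seed = 58,
                    n_iterations = 1200, burn_in = 200, thinning = 10)
  # residual variance fixed enormous: the likelihood carries no information,
  # so sampled alphas are prior draws (scaled t with nu df)
  ch <- run_chain(des, d, hy, model = "bayesA", fixed_sigma_e2 = 1e8,
                  store_draws = TRUE)
  draws <- as.vector(ch$alpha_draws) / sqrt(sa2)
  expect_gt(length(draws), 1e4)
  ks <- suppressWarnings(stats::ks.test(draws, function(q) pt(q, df = nu)))
  expect_gt(ks$p.value, 0.01)
})

test_that("predictions and their bookkeeping behave at the limits", {
  ds <- quick_dataset(n = 60, m = 40, seed = 59)
  d <- build_designs(ds$genotypes)
  hy <- bayes_hyper(n_iterations = 300, burn_in = 100, thinning = 2, seed = 4)
  chA <- run_chain(ds$design, d, hy, model = "bayesA")
  pv <- predict_genetic_values(chA, d)
  # BayesA: beta is identically zero, total equals breeding
  expect_identical(pv$total, pv$breeding)
  expect_identical(chA$beta_mean, rep(0, 40))
  # draw-count bookkeeping
  expect_identical(chA$n_kept, (300L - 100L) %/% 2L)
  # zero effects give zero predictions
  chA$alpha_mean <- rep(0, 40)
  chA$beta_mean <- rep(0, 40)
  pv0 <- predict_genetic_values(chA, d)
  expect_identical(pv0$total, rep(0, 60))
})
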
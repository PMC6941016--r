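test_that("heritability ratios follow their definitions", {
  h <- heritabilities(c(1, 0, 1))
  expect_equal(h$h2_narrow, 0.5)
  expect_equal(h$h2_dominance, 0)
  expect_equal(h$h2_broad, 0.5)
  h2 <- heritabilities(list(sigma_a2 = 2, sigma_d2 = 1, sigma_e2 = 1))
  expect_equal(h2$h2_narrow, 0.5)
  expect_equal(h2$h2_dominance, 0.25)
  expect_equal(h2$h2_broad, 0.75)
  expect_equal(h2$dominance_to_genetic, 1 / 3)
  expect_error(heritabilities(c(0, 0, 0)), "positive")
  expect_error(heritabilities(c(-1, 0.5, 1)), "nonnegative")
})

test_that("optimized restricted likelihood matches the error-contrast oracle", {
  ds <- quick_dataset(n = 80, m = 150, seed = 31)
  G <- stabilize(build_G(ds$genotypes), 1e-6)
  D <- stabilize(build_D(ds$genotypes), 1e-6)
  des <- ds$design
  vc <- reml_fit(des, list(G, D))
  V <- vc$sigma_a2 * G$values + vc$sigma_d2 * D$values +
    diag(vc$sigma_e2, 80)
  # the two REML criteria differ by the constant 0.5 log|X'X|
  const <- 0.5 * determinant(crossprod(des$X), logarithm = TRUE)$modulus
  expect_equal(vc$logL, as.numeric(reml_loglik_contrasts(des$y, des$X, V) - const),
               tolerance = 1e-6)
  # and the optimum is a stationary point: nearby components do worse
  for (bump in list(c(1.05, 1, 1), c(1, 1.1, 1), c(1, 1, 0.95))) {
    Vb <- bump[1] * vc$sigma_a2 * G$values + bump[2] * vc$sigma_d2 * D$values +
      diag(bump[3] * vc$sigma_e2, 80)
    expect_lte(as.numeric(reml_loglik_contrasts(des$y, des$X, Vb)),
               as.numeric(reml_loglik_contrasts(des$y, des$X, V)) + 1e-6)
  }
})

test_that("pure-noise phenotypes drive genetic components to the boundary", {
  ds <- quick_dataset(n = 150, m = 300, seed = 32, h2_additive = 0,
                      h2_dominance = 0)
  G <- stabilize(build_G(ds$genotypes), 1e-6)
  D <- stabilize(build_D(ds$genotypes), 1e-6)
  vc_a <- reml_fit(ds$design, list(G))
  vc_ad <- reml_fit(ds$design, list(G, D))
  tot <- vc_ad$sigma_a2 + vc_ad$sigma_d2 + vc_ad$sigma_e2
  expect_lt((vc_ad$sigma_a2 + vc_ad$sigma_d2) / tot, 0.15)
  expect_lt(vc_ad$logL - vc_a$logL, 2)
})

test_that("REML is translation invariant and scale equivariant", {
  ds <- quick_dataset(n = 100, m = 200, seed = 33)
  G <- stabilize(build_G(ds$genotypes), 1e-6)
  des <- ds$design
  vc <- reml_fit(des, list(G))
  des_shift <- trait_design(des$y + 1000, NULL)
  des_shift$X <- des$X
  vc_shift <- reml_fit(des_shift, list(G))
  expect_equal(vc_shift$sigma_a2, vc$sigma_a2, tolerance = 1e-3)
  expect_equal(vc_shift$sigma_e2, vc$sigma_e2, tolerance = 1e-3)
  des_scale <- trait_design(des$y * 3, NULL)
  des_scale$X <- des$X
  vc_scale <- reml_fit(des_scale, list(G))
  expect_equal(vc_scale$sigma_a2, 9 * vc$sigma_a2, tolerance = 1e-2)
  expect_equal(vc_scale$sigma_e2, 9 * vc$sigma_e2, tolerance = 1e-2)
})

test_that("MME solution equals direct GLS/BLUP by covariance inversion", {
  ds <- quick_dataset(n = 60, m = 120, seed = 34)
  G <- stabilize(build_G(ds$genotypes), 1e-6)
  D <- stabilize(build_D(ds$genotypes), 1e-6)
  des <- ds$design
  vc <- reml_fit(des, list(G, D))
  sol <- blup_solve(des, list(G, D), vc)
  # oracle: b = (X'V^-1 X)^-1 X'V^-1 y; u_i = sigma_i K_i V^-1 (y - X b)
  V <- vc$sigma_a2 * G$values + vc$sigma_d2 * D$values + diag(vc$sigma_e2, 60)
  Vinv <- solve(V)
  b <- solve(t(des$X) %*% Vinv %*% des$X, t(des$X) %*% Vinv %*% des$y)
  r <- des$y - des$X %*% b
  a <- vc$sigma_a2 * G$values %*% Vinv %*% r
  d <- vc$sigma_d2 * D$values %*% Vinv %*% r
  expect_equal(unname(sol$b_hat), unname(drop(b)), tolerance = 1e-6)
  expect_equal(sol$a_hat, drop(a), tolerance = 1e-6)
  expect_equal(sol$d_hat, drop(d), tolerance = 1e-6)
})

test_that("identity kinship with intercept-only design gives the shrinkage formula", {
  set.seed(35)
  n <- 40
  y <- rnorm(n, 10, 2)
  des <- trait_design(y, NULL)
  I_rel <- structure(list(values = diag(1, n), kind = "additive",
                          scale_denominator = 1, freqs_used = NULL, ridge = 0),
                     class = "relationship_matrix")
  vc <- list(sigma_a2 = 1.3, sigma_d2 = NA_real_, sigma_e2 = 0.7)
  sol <- blup_solve(des, list(I_rel), vc)
  shrink <- 1.3 / (1.3 + 0.7)
  expect_equal(sol$a_hat, shrink * (y - sol$b_hat), tolerance = 1e-8)
})

test_that("GBLUP equals SNP-BLUP ridge regression at the matched ratio", {
  ds <- quick_dataset(n = 70, m = 50, seed = 36)
  g <- ds$genotypes
  des <- ds$design
  G <- build_G(g)
  s2pq <- G$scale_denominator
  vc <- reml_fit(des, list(stabilize(G, 1e-8)))
  sol <- blup_solve(des, list(stabilize(G, 1e-8)), vc)
  # oracle: ridge regression of centred dosages with per-marker variance
  # sigma_a2 / sum(2pq), fixed effects estimated jointly by GLS
  M <- marker_codings(g)$M
  sigma_m2 <- vc$sigma_a2 / s2pq
  V <- sigma_m2 * tcrossprod(M) + diag(vc$sigma_e2, 70)
  Vinv <- solve(V)
  b <- solve(t(des$X) %*% Vinv %*% des$X, t(des$X) %*% Vinv %*% des$y)
  alpha <- sigma_m2 * t(M) %*% Vinv %*% (des$y - des$X %*% b)
  expect_equal(sol$a_hat, drop(M %*% alpha), tolerance = 1e-5)
})

test_that("vanishing dominance variance recovers the additive-only BLUP", {
  ds <- quick_dataset(n = 60, m = 120, seed = 37)
  G <- stabilize(build_G(ds$genotypes), 1e-6)
  D <- stabilize(build_D(ds$genotypes), 1e-6)
  des <- ds$design
  vc_a <- reml_fit(des, list(G))
  sol_a <- blup_solve(des, list(G), vc_a)
  vc_tiny <- list(sigma_a2 = vc_a$sigma_a2, sigma_d2 = 1e-12,
                  sigma_e2 = vc_a$sigma_e2)
  sol_full <- blup_solve(des, list(G, D), vc_tiny)
  expect_lt(max(abs(sol_full$a_hat - sol_a$a_hat)), 1e-6)
})

test_that("likelihood-ratio test handles boundary and reference cases", {
  eq <- likelihood_ratio_test(-100, -100)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p_value, 0.5)
  ref <- likelihood_ratio_test(-100, -98.08)
  expect_equal(ref$chi2, 3.84)
  expect_equal(ref$p_value_chi2_1df, 0.050, tolerance = 1e-2)
  expect_equal(ref$p_value, ref$p_value_chi2_1df / 2)
  expect_warning(neg <- likelihood_ratio_test(-100, -100.5), "clamped")
  expect_equal(neg$chi2, 0)
  expect_error(likelihood_ratio_test(NA, 0), "finite")
})

test_that("the dominance model never fits worse than the additive model", {
  for (s in 41:44) {
    ds <- quick_dataset(n = 120, m = 250, seed = s,
                        h2_additive = c(0.1, 0.42, 0.3, 0)[s - 40],
                        h2_dominance = c(0.3, 0.158, 0, 0.2)[s - 40])
    G <- stabilize(build_G(ds$genotypes), 1e-6)
    D <- stabilize(build_D(ds$genotypes), 1e-6)
    vc_a <- reml_fit(ds$design, list(G))
    vc_ad <- reml_fit(ds$design, list(G, D))
    expect_gte(vc_ad$logL, vc_a$logL - 1e-4)
    expect_gte(likelihood_ratio_test(vc_a$logL, vc_ad$logL)$chi2, 0)
  }
})
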
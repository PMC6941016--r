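# shared small dataset with relationship matrices for scan tests
gwas_fixture <- function(n = 300, m = 400, seed = 61, ...) {
  ds <- quick_dataset(n = n, m = m, seed = seed, ...)
  list(ds = ds,
       G = stabilize(build_G(ds$genotypes), 1e-6),
       D = stabilize(build_D(ds$genotypes), 1e-6))
}

test_that("GLS p-values agree with a brute-force explicit-inversion fit", {
  fx <- gwas_fixture(n = 50, m = 80)
  des <- fx$ds$ds <- fx$ds$design
  vc <- reml_fit(des, list(fx$G, fx$D))
  d <- build_designs(fx$ds$genotypes)
  V <- vc$sigma_a2 * fx$G$values + vc$sigma_d2 * fx$D$values +
    diag(vc$sigma_e2, 50)
  Vinv <- solve(V)
  for (j in c(3, 17, 42)) {
    res <- single_marker_test(des, list(fx$G, fx$D), vc, d$Wa[, j], d$Wb[, j])
    # oracle: GLS by explicit inversion, joint additive+dominance fit
    Xj <- cbind(des$X, d$Wa[, j], d$Wb[, j])
    XtVX <- t(Xj) %*% Vinv %*% Xj
    bhat <- solve(XtVX, t(Xj) %*% Vinv %*% des$y)
    covb <- solve(XtVX)
    q <- ncol(Xj)
    z2 <- bhat[c(q - 1, q)]^2 / diag(covb)[c(q - 1, q)]
    p_oracle <- pchisq(z2, df = 1, lower.tail = FALSE)
    expect_equal(res$p_additive, unname(p_oracle[1]), tolerance = 1e-8)
    expect_equal(res$p_dominance, unname(p_oracle[2]), tolerance = 1e-8)
    expect_equal(res$beta_additive, unname(bhat[q - 1]), tolerance = 1e-8)
  }
})

test_that("untestable markers are skipped or reduced gracefully", {
  fx <- gwas_fixture(n = 80, m = 60)
  des <- fx$ds$design
  vc <- reml_fit(des, list(fx$G))
  # zero-variance SNP: both codings constant
  res <- single_marker_test(des, list(fx$G), vc, rep(0, 80), rep(0, 80))
  expect_true(is.na(res$p_additive))
  expect_true(is.na(res$p_dominance))
  # no heterozygotes: dominance coding drops, additive p remains
  wa <- fx$ds$genotypes$dosages[, 5]
  wa2 <- ifelse(wa == 1L, 0L, wa) # strip heterozygotes
  res2 <- single_marker_test(des, list(fx$G), vc, wa2 - mean(wa2), rep(0, 80))
  expect_false(is.na(res2$p_additive))
  expect_true(is.na(res2$p_dominance))
})

test_that("an additive QTL is found as class A with a null dominance p", {
  counts <- vapply(1:8, function(s) {
    set.seed(800 + s)
    n <- 500
    g <- simulate_genotypes(sim_config(n_individuals = n, n_snps = 600,
                                       seed = 800 + s))
    cfg_bg <- sim_config(n_individuals = n, n_snps = 600, seed = 900 + s,
                         h2_additive = 0.25, h2_dominance = 0,
                         qtl_indices_additive = 1:50)
    ds <- simulate_phenotypes(g, cfg_bg)
    # mid-frequency QTL: additive and heterozygote codings near-orthogonal
    j <- which.min(abs(allele_frequencies(g) - 0.5))
    wa <- g$dosages[, j]
    qtl <- (wa - mean(wa)) * sqrt(0.2 * var(ds$phenotypes$trait) / var(wa))
    y <- ds$phenotypes$trait + qtl
    des <- trait_design(y, ds$phenotypes[, c("year", "sex", "entry_weight",
                                             "fattening_days")])
    G <- stabilize(build_G(g), 1e-6)
    hits <- mlmm_scan(des, g, list(G), scan_config(max_forward_steps = 3))
    any(hits$snp_id == g$snp_meta$snp_id[j] & hits$effect_class == "A")
  }, logical(1))
  expect_gte(mean(counts), 7 / 8)
})

test_that("an overdominant QTL is classified D and a mixed QTL A+D", {
  set.seed(62)
  n <- 600
  g <- simulate_genotypes(sim_config(n_individuals = n, n_snps = 800, seed = 62))
  cfg_bg <- sim_config(n_individuals = n, n_snps = 800, seed = 63,
                       h2_additive = 0.25, h2_dominance = 0.05)
  ds <- simulate_phenotypes(g, cfg_bg)
  vy <- var(ds$phenotypes$trait)
  covars <- ds$phenotypes[, c("year", "sex", "entry_weight", "fattening_days")]
  G <- stabilize(build_G(g), 1e-6)
  D <- stabilize(build_D(g), 1e-6)
  # mid-frequency loci so the two codings are not collinear
  ord <- order(abs(allele_frequencies(g) - 0.5))
  j_d <- ord[1]
  j_ad <- ord[2]

  # purely dominant locus: heterozygote deviation only
  het <- (g$dosages[, j_d] == 1) - mean(g$dosages[, j_d] == 1)
  y_d <- ds$phenotypes$trait + het * sqrt(0.15 * vy / var(het))
  hits_d <- mlmm_scan(trait_design(y_d, covars), g, list(G, D),
                      scan_config(max_forward_steps = 3))
  expect_true(any(hits_d$snp_id == g$snp_meta$snp_id[j_d] &
                    hits_d$effect_class == "D"))

  # locus with both additive and dominance action
  wa <- g$dosages[, j_ad] - mean(g$dosages[, j_ad])
  het2 <- (g$dosages[, j_ad] == 1) - mean(g$dosages[, j_ad] == 1)
  both <- wa * sqrt(0.10 * vy / var(wa)) + het2 * sqrt(0.10 * vy / var(het2))
  y_ad <- ds$phenotypes$trait + both
  hits_ad <- mlmm_scan(trait_design(y_ad, covars), g, list(G, D),
                       scan_config(max_forward_steps = 3))
  expect_true(any(hits_ad$snp_id == g$snp_meta$snp_id[j_ad] &
                    hits_ad$effect_class == "A+D"))
})

test_that("scan output is invariant to SNP input order", {
  fx <- gwas_fixture(n = 250, m = 300, seed = 64, h2_additive = 0.35,
                     h2_dominance = 0.1, n_qtl_additive = 3,
                     n_qtl_dominance = 3)
  des <- fx$ds$design
  hits1 <- mlmm_scan(des, fx$ds$genotypes, list(fx$G, fx$D),
                     scan_config(max_forward_steps = 4))
  perm <- sample(300)
  g2 <- subset_genotypes(fx$ds$genotypes, snps = perm)
  hits2 <- mlmm_scan(des, g2, list(fx$G, fx$D),
                     scan_config(max_forward_steps = 4))
  expect_setequal(hits1$snp_id, hits2$snp_id)
})

test_that("a single forward step with no signal returns no hits", {
  fx <- gwas_fixture(n = 150, m = 200, seed = 65, h2_additive = 0,
                     h2_dominance = 0)
  hits <- mlmm_scan(fx$ds$design, fx$ds$genotypes, list(fx$G),
                    scan_config(max_forward_steps = 1))
  expect_identical(nrow(hits), 0L)
  expect_equal(attr(hits, "threshold"), 0.05 / attr(hits, "n_tests"))
})

test_that("hit annotation applies the 100 kb nearest-gene rule", {
  genes <- data.frame(
    chrom = c("1", "1", "2"),
    start = c(100, 1000000, 5000),
    end = c(900, 1010000, 9000),
    name = c("GENE1", "GENE2", "GENE3"),
    stringsAsFactors = FALSE
  )
  hits <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4"),
    chrom = c("1", "1", "1", "2"),
    pos = c(500L, 1050000L, 500000L, 4000L),
    effect_class = "A", p_additive = 1e-8, p_dominance = NA,
    step_found = 1L, stringsAsFactors = FALSE
  )
  ann <- annotate_hits(hits, genes)
  # inside GENE1
  expect_equal(ann$relation[1], "within")
  expect_equal(ann$distance[1], 0)
  expect_equal(ann$gene_name[1], "GENE1")
  # 40 kb downstream of GENE2's end
  expect_equal(ann$relation[2], "downstream")
  expect_equal(ann$distance[2], 40000)
  # >100 kb from every gene on chromosome 1
  expect_equal(ann$relation[3], "none")
  expect_true(is.na(ann$gene_name[3]))
  # 1 kb upstream of GENE3 (0-based start 5000 -> first base 5001)
  expect_equal(ann$relation[4], "upstream")
  expect_equal(ann$distance[4], 1001)
  expect_error(annotate_hits(hits, transform(genes, end = start - 1)),
               "malformed")
})
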
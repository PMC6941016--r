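#' Simulation configuration
#'
#' Defines a synthetic population with known additive/dominance genetic
#' architecture.  Defaults emulate a Simmental-type fattening cohort of
#' 1233 animals at desk scale: a carcass-weight-like trait with
#' `h2_additive = 0.42` and `h2_dominance = 0.158`, fixed effects of
#' slaughter year (6 levels), sex (2 levels), body weight at entry to the
#' fattening unit, and number of fattening days.
#'
#' @param n_individuals number of individuals.
#' @param n_snps number of biallelic autosomal SNPs.
#' @param maf_range minor-allele-frequency range in `(0, 0.5]`; each SNP
#'   draws its own MAF uniformly on this range.
#' @param n_families number of full-sib families (0 = all unrelated).
#' @param sibs_per_family full sibs per family;
#'   `n_families * sibs_per_family <= n_individuals`.
#' @param n_qtl_additive,n_qtl_dominance numbers of QTLs with additive /
#'   dominance effects.
#' @param h2_additive,h2_dominance target in-sample fractions of the
#'   non-fixed phenotypic variance explained by breeding values and
#'   dominance deviations; their sum must be `< 1`.
#' @param trait_mean,trait_var intercept and total non-fixed phenotypic
#'   variance of the trait (defaults match a carcass-weight scale, kg and
#'   kg^2 after covariate adjustment).
#' @param fixed_effect_spec list of fixed-effect levels/ranges and their
#'   coefficients; see defaults in the function signature.
#' @param missing_rate fraction of genotype calls set to missing (after
#'   phenotypes are generated, so the truth is unaffected).
#' @param qtl_indices_additive,qtl_indices_dominance optional explicit QTL
#'   column indices (sampled when `NULL`).
#' @param seed integer seed; a single RNG stream drives the whole dataset.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1233, n_snps = 5000,
                       maf_range = c(0.05, 0.5),
                       n_families = 0, sibs_per_family = 0,
                       n_qtl_additive = min(100L, n_snps),
                       n_qtl_dominance = min(100L, n_snps),
                       h2_additive = 0.42, h2_dominance = 0.158,
                       trait_mean = 271.9, trait_var = 989.7,
                       fixed_effect_spec = list(
                         year_effects = c(0, 8, -5, 12, 3, -9),
                         sex_effects = c(0, 25),
                         entry_weight_range = c(180, 320),
                         entry_weight_coef = 0.15,
                         fattening_days_range = c(240L, 400L),
                         fattening_days_coef = 0.05
                       ),
                       missing_rate = 0,
                       qtl_indices_additive = NULL,
                       qtl_indices_dominance = NULL,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_snps >= 1)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (h2_additive < 0 || h2_dominance < 0 || h2_additive + h2_dominance >= 1) {
    stop("h2_additive + h2_dominance must be < 1 with nonnegative parts")
  }
  if (n_qtl_additive > n_snps || n_qtl_dominance > n_snps) {
    stop("number of QTLs cannot exceed n_snps")
  }
  if (n_families < 0 || sibs_per_family < 0 ||
      n_families * sibs_per_family > n_individuals) {
    stop("n_families * sibs_per_family must not exceed n_individuals")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate genotypes
#'
#' Unrelated individuals draw dosages as `Binomial(2, p)` per SNP, i.e.
#' Hardy-Weinberg genotype frequencies `(q^2, 2pq, p^2)`.  When
#' `n_families > 0`, the first `n_families * sibs_per_family` individuals
#' are full-sib groups: two HWE parents per family transmit one allele
#' each by Mendelian segregation.  Missing calls are injected at
#' `missing_rate` uniformly at random.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()]; attribute `family` carries the family id
#'   per individual (`NA` for unrelated), attribute `true_maf` the MAF each
#'   SNP was drawn with.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  n_fam_ind <- config$n_families * config$sibs_per_family
  dos <- matrix(0L, n, m)
  if (n_fam_ind < n) {
    idx <- (n_fam_ind + 1):n
    dos[idx, ] <- matrix(rbinom(length(idx) * m, 2L, rep(p, each = length(idx))),
                         nrow = length(idx))
  }
  family <- rep(NA_integer_, n)
  if (config$n_families > 0) {
    s <- config$sibs_per_family
    for (f in seq_len(config$n_families)) {
      rows <- (f - 1) * s + seq_len(s)
      family[rows] <- f
      sire <- rbinom(m, 2L, p)
      dam <- rbinom(m, 2L, p)
      for (r in rows) {
        dos[r, ] <- rbinom(m, 1L, sire / 2) + rbinom(m, 1L, dam / 2)
      }
    }
  }
  if (config$missing_rate > 0) {
    drop <- runif(length(dos)) < config$missing_rate
    dos[drop] <- NA_integer_
  }
  chrom <- sort(rep_len(1:29, m)) # 29 bovine autosomes
  pos <- as.integer(stats::ave(seq_len(m), chrom, FUN = seq_along)) * 50000L
  geno <- genotype_matrix(
    dos,
    snp_meta = data.frame(
      chrom = as.character(chrom),
      snp_id = sprintf("snp%05d", seq_len(m)),
      pos = pos,
      allele1 = "A", allele2 = "B", stringsAsFactors = FALSE
    ),
    individual_ids = sprintf("ind%04d", seq_len(n))
  )
  attr(geno, "family") <- family
  attr(geno, "true_maf") <- p
  geno
}

#' Simulate phenotypes with known additive/dominance architecture
#'
#' QTL effects are drawn standard normal; per-individual breeding values
#' use the centred additive coding and dominance deviations the centred
#' heterozygosity coding (the same codings the relationship matrices use,
#' so the GREML model is correctly specified).  Genetic parts are rescaled
#' so the realised in-sample variance fractions equal the `h2` targets
#' exactly; the residual is drawn orthogonal (in sample) to both genetic
#' parts and scaled so the total non-fixed variance equals `trait_var`.
#'
#' @param geno a [genotype_matrix()] (missing calls at QTLs are mean-imputed
#'   for the truth computation).
#' @param config a [sim_config()].
#' @return list of class `simulated_dataset`: `genotypes`, `phenotypes`
#'   (data frame: id, trait, year, sex, entry_weight, fattening_days),
#'   `true_breeding_values`, `true_dominance_deviations`, `true_qtl_table`
#'   (snp_index, a, d), and the `config`.
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 500009L) # same stream family, distinct from genotype draw
  n <- n_ind(geno)
  m <- n_snp(geno)
  V <- config$trait_var

  qa <- config$qtl_indices_additive
  if (is.null(qa)) qa <- sort(sample.int(m, config$n_qtl_additive))
  qd <- config$qtl_indices_dominance
  if (is.null(qd)) qd <- sort(sample.int(m, config$n_qtl_dominance))

  used <- sort(unique(c(qa, qd)))
  sub <- geno$dosages[, used, drop = FALSE]
  if (anyNA(sub)) { # mean-impute for truth computation only
    for (j in seq_along(used)) {
      col <- sub[, j]
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      sub[, j] <- col
    }
  }
  p_used <- colMeans(sub) / 2
  tpq <- 2 * p_used * (1 - p_used)
  Mq <- sweep(sub, 2L, 2 * p_used, "-")
  Hq <- sweep((geno$dosages[, used, drop = FALSE] == 1L) * 1.0, 2L, tpq, "-")
  Hq[is.na(Hq)] <- 0

  a_raw <- numeric(length(used))
  d_raw <- numeric(length(used))
  a_raw[match(qa, used)] <- rnorm(length(qa))
  d_raw[match(qd, used)] <- rnorm(length(qd))

  tbv <- drop(Mq %*% a_raw)
  dom <- drop(Hq %*% d_raw)
  scale_part <- function(g, h2) {
    if (h2 == 0) return(list(g = rep(0, n), s = 0))
    vg <- var(g)
    if (vg <= 0) stop("zero genetic variance with a nonzero heritability target")
    s <- sqrt(h2 * V / vg)
    list(g = g * s, s = s)
  }
  sa <- scale_part(tbv, config$h2_additive)
  sd_ <- scale_part(dom, config$h2_dominance)
  tbv <- sa$g
  dom <- sd_$g

  # residual orthogonal in sample to both genetic parts, variance topped up
  # so the realised variance fractions are exact
  e <- rnorm(n)
  B <- cbind(1, tbv, dom)
  B <- B[, c(TRUE, sd(tbv) > 0, sd(dom) > 0), drop = FALSE]
  e <- lm.fit(B, e)$residuals
  var_e_target <- V - var(tbv + dom)
  if (var_e_target < 0) {
    stop("h2 targets unreachable: genetic covariance exceeds the residual budget")
  }
  e <- if (var(e) > 0) drop(e) * sqrt(var_e_target / var(e)) else rep(0, n)

  fe <- config$fixed_effect_spec
  year <- factor(sample(seq_along(fe$year_effects), n, replace = TRUE))
  sex <- factor(sample(seq_along(fe$sex_effects), n, replace = TRUE))
  entry_weight <- runif(n, fe$entry_weight_range[1], fe$entry_weight_range[2])
  fattening_days <- sample(fe$fattening_days_range[1]:fe$fattening_days_range[2],
                           n, replace = TRUE)
  fixed_part <- config$trait_mean +
    fe$year_effects[as.integer(year)] + fe$sex_effects[as.integer(sex)] +
    fe$entry_weight_coef * entry_weight + fe$fattening_days_coef * fattening_days

  y <- fixed_part + tbv + dom + e

  truth <- data.frame(snp_index = used,
                      a = a_raw * sa$s, d = d_raw * sd_$s)
  truth <- truth[truth$a != 0 | truth$d != 0, , drop = FALSE]
  rownames(truth) <- NULL

  structure(
    list(
      genotypes = geno,
      phenotypes = data.frame(
        id = geno$individual_ids, trait = y, year = year, sex = sex,
        entry_weight = entry_weight, fattening_days = fattening_days,
        stringsAsFactors = FALSE
      ),
      fixed_part = fixed_part,
      true_breeding_values = tbv,
      true_dominance_deviations = dom,
      true_qtl_table = truth,
      config = config
    ),
    class = "simulated_dataset"
  )
}

#' Simulate a full dataset (genotypes, then phenotypes, then missingness)
#'
#' Convenience wrapper: genotypes are simulated without missing calls,
#' phenotypes computed from the complete matrix, and missing calls injected
#' afterwards so the recorded truth is unaffected by missingness.
#'
#' @param config a [sim_config()].
#' @return A `simulated_dataset`; see [simulate_phenotypes()].
#' @export
simulate_dataset <- function(config) {
  cfg_full <- config
  cfg_full$missing_rate <- 0
  geno <- simulate_genotypes(cfg_full)
  ds <- simulate_phenotypes(geno, cfg_full)
  if (config$missing_rate > 0) {
    set.seed(config$seed + 900007L)
    dos <- ds$genotypes$dosages
    dos[runif(length(dos)) < config$missing_rate] <- NA_integer_
    fam <- attr(ds$genotypes, "family")
    ds$genotypes$dosages <- dos
    attr(ds$genotypes, "family") <- fam
    ds$config <- config
  }
  ds
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d individuals x %d SNPs, %d QTLs, h2_a = %.3f, h2_d = %.3f (seed %d)\n",
    n_ind(x$genotypes), n_snp(x$genotypes), nrow(x$true_qtl_table),
    x$config$h2_additive, x$config$h2_dominance, x$config$seed
  ))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' PLINK bed/bim/fam plus a tab-delimited phenotype/covariate table
#' (`<prefix>.pheno.tsv`) and the true QTL table (`<prefix>.qtl.tsv`).
#'
#' @param dataset a `simulated_dataset`.
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  write_plink(dataset$genotypes, prefix)
  write_pheno(dataset$phenotypes, paste0(prefix, ".pheno.tsv"))
  write.table(dataset$true_qtl_table, paste0(prefix, ".qtl.tsv"),
              quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam", ".pheno.tsv", ".qtl.tsv")))
}
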
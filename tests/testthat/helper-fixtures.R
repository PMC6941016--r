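# Shared fixtures built in code.

# Small genotype matrix with explicit dosages (rows = individuals).
toy_geno <- function(dosages, chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  meta <- data.frame(
    chrom = if (is.null(chrom)) rep("1", m) else as.character(chrom),
    snp_id = sprintf("t%03d", seq_len(m)),
    pos = if (is.null(pos)) seq_len(m) * 1000L else as.integer(pos),
    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE
  )
  genotype_matrix(dosages, snp_meta = meta)
}

# Simulated dataset together with the matching trait design.
quick_dataset <- function(n = 200, m = 400, seed = 1, ...) {
  args <- list(n_individuals = n, n_snps = m, seed = seed, ...)
  if (is.null(args$n_qtl_additive)) args$n_qtl_additive <- min(100L, m %/% 2)
  if (is.null(args$n_qtl_dominance)) args$n_qtl_dominance <- min(100L, m %/% 2)
  ds <- simulate_dataset(do.call(sim_config, args))
  ph <- ds$phenotypes
  ds$design <- trait_design(
    ph$trait, ph[, c("year", "sex", "entry_weight", "fattening_days")],
    ids = ph$id
  )
  ds
}

# Dense-matrix restricted log-likelihood via error contrasts: an
# independent route to the REML criterion.  A is an orthonormal basis of
# the orthogonal complement of col(X), so the value differs from the
# profile form by the constant 0.5 * log|X'X|.
reml_loglik_contrasts <- function(y, X, V) {
  n <- length(y)
  A <- qr.Q(qr(X), complete = TRUE)[, (qr(X)$rank + 1):n, drop = FALSE]
  AVA <- crossprod(A, V %*% A)
  Ay <- crossprod(A, y)
  -0.5 * (determinant(AVA, logarithm = TRUE)$modulus +
            drop(crossprod(Ay, solve(AVA, Ay))))
}
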
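#' Observed allele frequencies
#'
#' Frequency of the second (`allele2`) allele per SNP, computed from
#' non-missing calls.
#'
#' @param geno a [genotype_matrix()].
#' @return numeric vector of length `m` in `[0, 1]`.
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n_obs <- colSums(!is.na(geno$dosages))
  if (any(n_obs == 0)) {
    stop("SNPs with all calls missing: ",
         paste(geno$snp_meta$snp_id[n_obs == 0], collapse = ", "))
  }
  colSums(geno$dosages, na.rm = TRUE) / (2 * n_obs)
}

#' Marker codings for relationship matrices
#'
#' Builds the centred additive coding `M` (dosage minus `2p`) and the
#' centred heterozygosity coding `H` (heterozygote indicator minus `2pq`).
#' Missing dosages contribute 0 after centring (mean imputation).
#'
#' @param geno a [genotype_matrix()].
#' @param freqs allele-2 frequencies; computed from `geno` when omitted.
#' @return list with `M`, `H` (n x m numeric matrices) and `freqs`.
#' @export
marker_codings <- function(geno, freqs = allele_frequencies(geno)) {
  dos <- geno$dosages
  p <- freqs
  M <- sweep(ifelse(is.na(dos), rep(2 * p, each = nrow(dos)), dos),
             2L, 2 * p, "-")
  het <- (dos == 1L) * 1.0
  het[is.na(het)] <- rep(2 * p * (1 - p), each = nrow(dos))[is.na(dos)]
  H <- sweep(het, 2L, 2 * p * (1 - p), "-")
  list(M = M, H = H, freqs = p)
}

.relationship_matrix <- function(values, kind, denom, freqs, ridge = 0) {
  structure(
    list(values = values, kind = kind, scale_denominator = denom,
         freqs_used = freqs, ridge = ridge),
    class = "relationship_matrix"
  )
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s genomic relationship matrix: %d x %d (denominator %.4g, ridge %g)\n",
              x$kind, nrow(x$values), ncol(x$values), x$scale_denominator, x$ridge))
  invisible(x)
}

#' Additive genomic relationship matrix
#'
#' `G = M M' / sum(2 p_i q_i)` with `M` the centred additive coding
#' (VanRaden-type normalisation).  For unrelated non-inbred individuals in
#' Hardy-Weinberg proportions the expected diagonal is 1 and the expected
#' off-diagonal 0.
#'
#' @param geno a [genotype_matrix()].
#' @param freqs allele-2 frequencies used for centring and scaling;
#'   observed sample frequencies by default, recorded in the result.
#' @return A `relationship_matrix` with `kind = "additive"`.
#' @export
build_G <- function(geno, freqs = allele_frequencies(geno)) {
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("monomorphic SNPs present; apply QC before building G")
  }
  denom <- sum(2 * freqs * (1 - freqs))
  if (denom <= 0) stop("zero denominator: all SNPs monomorphic")
  cod <- marker_codings(geno, freqs)
  .relationship_matrix(tcrossprod(cod$M) / denom, "additive", denom, freqs)
}

#' Dominance genomic relationship matrix
#'
#' `D = H H' / sum(2 p_i q_i (1 - 2 p_i q_i))` with `H` the heterozygosity
#' coding centred by `2 p_i q_i`.  With this centring and scaling the
#' expected diagonal is 1 for a non-inbred individual and the expected
#' off-diagonal 0 for two unrelated individuals.
#'
#' @inheritParams build_G
#' @return A `relationship_matrix` with `kind = "dominance"`.
#' @export
build_D <- function(geno, freqs = allele_frequencies(geno)) {
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("monomorphic SNPs present; apply QC before building D")
  }
  tpq <- 2 * freqs * (1 - freqs)
  denom <- sum(tpq * (1 - tpq))
  if (denom <= 0) stop("zero denominator for D (all SNPs at 2pq in {0, 1})")
  cod <- marker_codings(geno, freqs)
  .relationship_matrix(tcrossprod(cod$H) / denom, "dominance", denom, freqs)
}

#' Ridge-stabilise a relationship matrix
#'
#' Adds `ridge` to the diagonal and verifies positive definiteness by a
#' Cholesky factorisation.
#'
#' @param rel a `relationship_matrix`.
#' @param ridge nonnegative scalar added to the diagonal.
#' @return The stabilised `relationship_matrix` (ridge recorded).
#' @export
stabilize <- function(rel, ridge = 1e-6) {
  stopifnot(inherits(rel, "relationship_matrix"), ridge >= 0)
  out <- rel
  if (ridge > 0) out$values <- rel$values + diag(ridge, nrow(rel$values))
  out$ridge <- rel$ridge + ridge
  ok <- tryCatch({ chol(out$values); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop("matrix not positive definite after ridge ", ridge,
         "; increase the ridge")
  }
  out
}

#' Write a relationship matrix as TSV (small n)
#' @param rel a `relationship_matrix`.
#' @param path output file.
#' @param ids individual ids used as row/column names.
#' @export
write_grm_tsv <- function(rel, path, ids = NULL) {
  v <- rel$values
  if (!is.null(ids)) dimnames(v) <- list(ids, ids)
  write.table(format(v, digits = 10), path, quote = FALSE, sep = "\t",
              col.names = NA)
  invisible(path)
}
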
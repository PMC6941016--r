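#' Genotype matrix container
#'
#' An `n x m` matrix of additive dosage codes counting copies of the second
#' (alternative, `allele2`) allele: 0 for `A1A1`, 1 for the heterozygote, 2
#' for `A2A2`, `NA` for a missing call.  Rows are individuals, columns SNPs.
#'
#' @param dosages integer (or coercible) matrix with entries in
#'   `{0, 1, 2, NA}`.
#' @param snp_meta data frame with one row per SNP and columns `chrom`,
#'   `snp_id`, `pos`, `allele1`, `allele2`.  Generated when omitted.
#' @param individual_ids character vector of unique sample identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snp_meta`, `individual_ids`.
#' @export
genotype_matrix <- function(dosages, snp_meta = NULL, individual_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(individual_ids)) individual_ids <- sprintf("ind%04d", seq_len(n))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != n) stop("individual_ids length != nrow(dosages)")
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(
      chrom = rep("1", m),
      snp_id = sprintf("snp%05d", seq_len(m)),
      pos = seq_len(m) * 1000L,
      allele1 = rep("A", m),
      allele2 = rep("B", m),
      stringsAsFactors = FALSE
    )
  }
  required <- c("chrom", "snp_id", "pos", "allele1", "allele2")
  if (!all(required %in% names(snp_meta))) {
    stop("snp_meta must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(snp_meta) != m) stop("snp_meta rows != ncol(dosages)")
  dup <- snp_meta$snp_id[duplicated(snp_meta$snp_id)]
  if (length(dup)) stop("duplicate SNP ids: ", paste(unique(dup), collapse = ", "))
  if (any(snp_meta$pos < 0)) stop("SNP positions must be nonnegative")
  snp_meta$chrom <- as.character(snp_meta$chrom)
  rownames(snp_meta) <- NULL
  structure(
    list(dosages = dosages, snp_meta = snp_meta, individual_ids = individual_ids),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x$dosages)
  miss <- mean(is.na(x$dosages))
  cat(sprintf(
    "genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
    d[1], d[2], 100 * miss
  ))
  invisible(x)
}

n_ind <- function(geno) nrow(geno$dosages)
n_snp <- function(geno) ncol(geno$dosages)

#' Subset a genotype matrix
#'
#' @param geno a [genotype_matrix()].
#' @param individuals,snps index vectors (integer, logical, or ids/names);
#'   `NULL` keeps everything.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(geno, individuals = NULL, snps = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ii <- if (is.null(individuals)) seq_len(n_ind(geno)) else individuals
  if (is.character(ii)) ii <- match(ii, geno$individual_ids)
  jj <- if (is.null(snps)) seq_len(n_snp(geno)) else snps
  if (is.character(jj)) jj <- match(jj, geno$snp_meta$snp_id)
  genotype_matrix(
    geno$dosages[ii, jj, drop = FALSE],
    snp_meta = geno$snp_meta[jj, , drop = FALSE],
    individual_ids = geno$individual_ids[ii]
  )
}
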
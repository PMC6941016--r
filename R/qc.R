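#' Quality-control thresholds
#'
#' Filters mirror routine SNP-array QC for association and prediction work:
#' SNPs are kept when minor allele frequency is strictly above `min_maf`,
#' call missingness strictly below `max_snp_missing`, and the exact
#' Hardy-Weinberg test p-value strictly above `min_hwe_p`; individuals with
#' missingness above `max_ind_missing` are dropped first.
#'
#' @param min_maf minimum minor allele frequency (exclusive), default 0.05.
#' @param max_snp_missing maximum per-SNP missing fraction (exclusive),
#'   default 0.05.
#' @param min_hwe_p minimum exact HWE p-value (exclusive), default `1e-6`.
#' @param max_ind_missing maximum per-individual missing fraction
#'   (exclusive above), default 0.10.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.05, max_snp_missing = 0.05,
                          min_hwe_p = 1e-6, max_ind_missing = 0.10) {
  vals <- c(min_maf, max_snp_missing, min_hwe_p, max_ind_missing)
  if (any(vals < 0) || any(vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(
    list(min_maf = min_maf, max_snp_missing = max_snp_missing,
         min_hwe_p = min_hwe_p, max_ind_missing = max_ind_missing),
    class = "qc_thresholds"
  )
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of heterozygote counts whose conditional probability
#' does not exceed that of the observed count.  Matches the standard exact
#' test used by PLINK (no mid-p adjustment).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in `[0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped individual required")
  nA <- 2 * n_AA + n_Aa # copies of the rarer-or-not allele A; symmetry in A/a
  if (nA > n) nA <- 2 * n - nA # work with the minor allele
  # possible heterozygote counts share the parity of nA
  hets <- seq(nA %% 2, nA, by = 2)
  # log P(h het | n, nA) up to a shared constant
  logp <- hets * log(2) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (nA + hets) / 2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Per-SNP summary used by QC
#' @noRd
.snp_qc_stats <- function(dosages) {
  n_obs <- colSums(!is.na(dosages))
  miss <- 1 - n_obs / nrow(dosages)
  alt <- colSums(dosages, na.rm = TRUE)
  p <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  maf <- pmin(p, 1 - p)
  n_het <- colSums(dosages == 1L, na.rm = TRUE)
  n_hom_alt <- colSums(dosages == 2L, na.rm = TRUE)
  n_hom_ref <- n_obs - n_het - n_hom_alt
  list(miss = miss, maf = maf,
       n_hom_ref = n_hom_ref, n_het = n_het, n_hom_alt = n_hom_alt)
}

#' Apply quality control to a genotype matrix
#'
#' Filters are applied in a fixed order so that removal counts are
#' well-defined: (1) individual missingness, (2) SNP missingness, (3) minor
#' allele frequency, (4) exact HWE — each SNP is attributed to the first
#' criterion it fails.  SNP statistics use non-missing calls of the
#' surviving individuals only; no imputation happens at this stage.
#' Passes repeat until no further removals occur (removing SNPs can push an
#' individual over its missingness threshold and vice versa), which makes
#' the operation idempotent.
#'
#' @param geno a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return A list with elements `genotypes` (filtered [genotype_matrix()])
#'   and `report` (class `qc_report`): counts removed per criterion and
#'   survivor counts.
#' @export
apply_qc <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  n0 <- n_ind(geno)
  m0 <- n_snp(geno)
  keep_ind <- rep(TRUE, n0)
  keep_snp <- rep(TRUE, m0)
  removed_ind <- 0L
  removed_miss <- 0L
  removed_maf <- 0L
  removed_hwe <- 0L
  hwe_p <- rep(NA_real_, m0)

  # passes repeat until stable, because removing SNPs can change individual
  # missingness and vice versa; this makes QC idempotent
  repeat {
    changed <- FALSE
    ind_miss <- rowMeans(is.na(geno$dosages[, keep_snp, drop = FALSE]))
    drop_ind <- keep_ind & ind_miss > thresholds$max_ind_missing
    if (any(drop_ind)) {
      keep_ind[drop_ind] <- FALSE
      removed_ind <- removed_ind + sum(drop_ind)
      changed <- TRUE
    }
    if (!any(keep_ind)) stop("QC removed every individual")

    st <- .snp_qc_stats(geno$dosages[keep_ind, , drop = FALSE])
    fail_miss <- keep_snp & st$miss >= thresholds$max_snp_missing
    fail_maf <- keep_snp & !fail_miss &
      (is.na(st$maf) | st$maf <= thresholds$min_maf)
    candidates <- which(keep_snp & !fail_miss & !fail_maf)
    for (j in candidates) {
      hwe_p[j] <- hwe_exact_test(st$n_hom_ref[j], st$n_het[j], st$n_hom_alt[j])
    }
    fail_hwe <- keep_snp & !fail_miss & !fail_maf &
      !is.na(hwe_p) & hwe_p <= thresholds$min_hwe_p
    drop_snp <- fail_miss | fail_maf | fail_hwe
    if (any(drop_snp)) {
      keep_snp[drop_snp] <- FALSE
      removed_miss <- removed_miss + sum(fail_miss)
      removed_maf <- removed_maf + sum(fail_maf)
      removed_hwe <- removed_hwe + sum(fail_hwe)
      changed <- TRUE
    }
    if (!any(keep_snp)) stop("QC removed every SNP")
    if (!changed) break
  }

  out <- genotype_matrix(
    geno$dosages[keep_ind, keep_snp, drop = FALSE],
    snp_meta = geno$snp_meta[keep_snp, , drop = FALSE],
    individual_ids = geno$individual_ids[keep_ind]
  )
  report <- structure(
    list(
      n_individuals_in = n0, n_snps_in = m0,
      individuals_removed = removed_ind,
      snps_removed_missing = removed_miss,
      snps_removed_maf = removed_maf,
      snps_removed_hwe = removed_hwe,
      n_individuals_out = sum(keep_ind),
      n_snps_out = sum(keep_snp),
      hwe_p = hwe_p
    ),
    class = "qc_report"
  )
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d individuals kept, %d/%d SNPs kept\n",
              x$n_individuals_out, x$n_individuals_in,
              x$n_snps_out, x$n_snps_in))
  cat(sprintf("  removed: %d individuals (missingness), %d SNPs (missingness), %d (MAF), %d (HWE)\n",
              x$individuals_removed, x$snps_removed_missing,
              x$snps_removed_maf, x$snps_removed_hwe))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [apply_qc()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("individuals_in", "individuals_removed", "individuals_out",
               "snps_in", "snps_removed_missing", "snps_removed_maf",
               "snps_removed_hwe", "snps_out"),
    value = c(report$n_individuals_in, report$individuals_removed,
              report$n_individuals_out, report$n_snps_in,
              report$snps_removed_missing, report$snps_removed_maf,
              report$snps_removed_hwe, report$n_snps_out)
  )
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
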
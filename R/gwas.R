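#' Configuration for the multi-locus mixed-model scan
#'
#' @param significance_threshold per-test significance level.  The default
#'   `"bonferroni"` resolves to `0.05 / (number of tests)` at scan time,
#'   where the number of tests counts every p-value computed (additive and,
#'   when tested, dominance codings).  A numeric value overrides this.
#' @param max_forward_steps maximum number of forward-inclusion steps.
#' @param variance_strategy `"refit-per-step"` re-estimates the variance
#'   components after each cofactor inclusion (the faithful multi-locus
#'   procedure); `"fixed-after-null"` keeps the null-model components.
#' @param include_dominance_kinship include the dominance relationship
#'   matrix as a second random component when available.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(significance_threshold = "bonferroni",
                        max_forward_steps = 10L,
                        variance_strategy = c("refit-per-step", "fixed-after-null"),
                        include_dominance_kinship = TRUE) {
  if (is.numeric(significance_threshold) &&
      (significance_threshold <= 0 || significance_threshold >= 1)) {
    stop("significance_threshold must lie in (0, 1)")
  }
  if (max_forward_steps < 1) stop("max_forward_steps must be >= 1")
  structure(
    list(significance_threshold = significance_threshold,
         max_forward_steps = as.integer(max_forward_steps),
         variance_strategy = match.arg(variance_strategy),
         include_dominance_kinship = include_dominance_kinship),
    class = "scan_config"
  )
}

# phenotypic covariance at the fitted components
.gwas_vcov <- function(vc, matrices) {
  n <- nrow(matrices[[1]]$values)
  V <- vc$sigma_a2 * matrices[[1]]$values + diag(vc$sigma_e2, n)
  if (length(matrices) == 2 && !is.na(vc$sigma_d2)) {
    V <- V + vc$sigma_d2 * matrices[[2]]$values
  }
  V
}

# whiten columns: z = R'^-1 x where V = R'R (R upper Cholesky)
.whiten <- function(R, x) backsolve(R, x, transpose = TRUE)

# Vectorised generalized-least-squares scan of all SNPs.
# Returns per-SNP marginal Wald p-values for the additive and dominance
# codings entered jointly, plus effect estimates.
.gls_scan <- function(y, X, Wa, Wb, V, tol = 1e-8) {
  R <- chol(V)
  yw <- .whiten(R, y)
  Xw <- .whiten(R, X)
  Waw <- .whiten(R, Wa)
  Wbw <- .whiten(R, Wb)
  qrX <- qr(Xw)
  yr <- qr.resid(qrX, yw)
  War <- qr.resid(qrX, Waw)
  Wbr <- qr.resid(qrX, Wbw)
  Saa <- colSums(War^2)
  Sdd <- colSums(Wbr^2)
  Sad <- colSums(War * Wbr)
  Say <- colSums(War * yr)
  Sdy <- colSums(Wbr * yr)
  m <- ncol(Wa)
  p_add <- rep(NA_real_, m)
  p_dom <- rep(NA_real_, m)
  beta_add <- rep(NA_real_, m)
  beta_dom <- rep(NA_real_, m)
  scale_a <- max(Saa, 1)
  scale_d <- max(Sdd, 1)
  det2 <- Saa * Sdd - Sad^2
  joint <- Saa > tol * scale_a & Sdd > tol * scale_d & det2 > tol^2 * scale_a * scale_d
  addonly <- !joint & Saa > tol * scale_a
  # joint 2-coefficient fit; whitened noise has unit variance so Wald uses
  # the known-variance normal reference
  if (any(joint)) {
    j <- joint
    ba <- (Sdd[j] * Say[j] - Sad[j] * Sdy[j]) / det2[j]
    bd <- (Saa[j] * Sdy[j] - Sad[j] * Say[j]) / det2[j]
    va <- Sdd[j] / det2[j]
    vd <- Saa[j] / det2[j]
    beta_add[j] <- ba
    beta_dom[j] <- bd
    p_add[j] <- pchisq(ba^2 / va, df = 1, lower.tail = FALSE)
    p_dom[j] <- pchisq(bd^2 / vd, df = 1, lower.tail = FALSE)
  }
  if (any(addonly)) {
    j <- addonly
    ba <- Say[j] / Saa[j]
    beta_add[j] <- ba
    p_add[j] <- pchisq(ba^2 * Saa[j], df = 1, lower.tail = FALSE)
  }
  list(p_additive = p_add, p_dominance = p_dom,
       beta_additive = beta_add, beta_dominance = beta_dom)
}

#' Single-marker mixed-model association test
#'
#' Generalised least squares with covariance
#' `sigma_a2 G (+ sigma_d2 D) + sigma_e2 I`: the tested SNP's additive and
#' dominance codings enter jointly and each coefficient gets a marginal
#' Wald p-value.  The dominance coding is dropped (p-value `NA`) when the
#' SNP has no heterozygotes (or no dominance variation after projection).
#'
#' @param design a [trait_design()].
#' @param matrices list of `relationship_matrix` objects (G, optionally D).
#' @param vc `variance_components` estimated under the current cofactor
#'   set.
#' @param wa,wd numeric vectors: additive (dosage) and dominance
#'   (heterozygote) codings of the tested SNP.
#' @param cofactors optional matrix of fixed-effect SNP columns to adjust
#'   for.
#' @return list with `p_additive`, `p_dominance`, `beta_additive`,
#'   `beta_dominance`.
#' @export
single_marker_test <- function(design, matrices, vc, wa, wd, cofactors = NULL) {
  if (inherits(matrices, "relationship_matrix")) matrices <- list(matrices)
  X <- design$X
  if (!is.null(cofactors)) X <- cbind(X, cofactors)
  V <- .gwas_vcov(vc, matrices)
  res <- .gls_scan(design$y, X, cbind(wa), cbind(wd), V)
  lapply(res, `[`, 1L)
}

#' Multi-locus mixed-model association scan
#'
#' Stepwise scan with forward inclusion and backward elimination of
#' markers as fixed-effect cofactors while a polygenic random effect
#' (G, optionally plus D) controls relatedness.  Each step scans every
#' non-cofactor SNP (additive and dominance codings jointly), adds the
#' most significant SNP if it passes the threshold, and re-estimates the
#' variance components (per `variance_strategy`).  After the forward
#' phase, cofactors whose p-values exceed the threshold in the final model
#' are removed.  Surviving hits are classified `A`, `D`, or `A+D` by which
#' coding(s) pass the threshold.
#'
#' Ties on the p-value are broken by larger absolute effect, then by
#' (chromosome, position).
#'
#' @param design a [trait_design()].
#' @param geno a [genotype_matrix()] (post-QC).
#' @param matrices list of `relationship_matrix` objects (G first,
#'   D second when used).
#' @param config a [scan_config()].
#' @return data frame of class `gwas_hits` with columns `snp_id`, `chrom`,
#'   `pos`, `effect_class`, `p_additive`, `p_dominance`, `step_found`;
#'   attributes `threshold` and `n_tests`.
#' @export
mlmm_scan <- function(design, geno, matrices, config = scan_config()) {
  stopifnot(inherits(design, "trait_design"), inherits(geno, "genotype_matrix"))
  if (inherits(matrices, "relationship_matrix")) matrices <- list(matrices)
  if (!config$include_dominance_kinship && length(matrices) == 2) {
    matrices <- matrices[1]
  }
  d <- build_designs(geno)
  Wa <- d$Wa
  Wb <- d$Wb
  m <- ncol(Wa)
  n <- nrow(Wa)
  test_dom <- colSums(Wb != 0) > 0
  n_tests <- m + sum(test_dom)
  threshold <- config$significance_threshold
  if (identical(threshold, "bonferroni")) threshold <- 0.05 / n_tests

  meta <- geno$snp_meta
  cof <- integer(0) # cofactor SNP indices, in inclusion order
  step_found <- integer(0)

  fit_vc <- function(cof_idx) {
    Xa <- design$X
    if (length(cof_idx)) {
      extra <- cbind(Wa[, cof_idx, drop = FALSE],
                     Wb[, cof_idx[test_dom[cof_idx]], drop = FALSE])
      keep <- qr(cbind(Xa, extra))$rank == ncol(Xa) + ncol(extra)
      if (!keep) { # drop collinear cofactor columns
        Q <- qr(cbind(Xa, extra))
        sel <- Q$pivot[seq_len(Q$rank)]
        full <- cbind(Xa, extra)[, sort(sel), drop = FALSE]
        return(reml_fit(structure(list(y = design$y, X = full, ids = design$ids),
                                  class = "trait_design"), matrices))
      }
      Xa <- cbind(Xa, extra)
    }
    reml_fit(structure(list(y = design$y, X = Xa, ids = design$ids),
                       class = "trait_design"), matrices)
  }

  vc <- fit_vc(integer(0))
  vc_current <- vc

  pick_best <- function(scan, candidates) {
    pmin_snp <- pmin(scan$p_additive[candidates], scan$p_dominance[candidates],
                     na.rm = TRUE)
    pmin_snp[is.na(scan$p_additive[candidates]) &
               is.na(scan$p_dominance[candidates])] <- Inf
    best_p <- min(pmin_snp)
    if (!is.finite(best_p)) return(NULL)
    tied <- candidates[pmin_snp <= best_p * (1 + 1e-12)]
    if (length(tied) > 1) {
      eff <- pmax(abs(scan$beta_additive[tied]), abs(scan$beta_dominance[tied]),
                  na.rm = TRUE)
      tied <- tied[order(-eff, meta$chrom[tied], meta$pos[tied])]
    }
    list(idx = tied[1], p = best_p)
  }

  for (step in seq_len(config$max_forward_steps)) {
    candidates <- setdiff(seq_len(m), cof)
    if (!length(candidates)) break
    Xc <- design$X
    if (length(cof)) {
      Xc <- cbind(Xc, Wa[, cof, drop = FALSE],
                  Wb[, cof[test_dom[cof]], drop = FALSE])
    }
    V <- .gwas_vcov(vc_current, matrices)
    scan <- .gls_scan(design$y, Xc, Wa, Wb, V)
    scan$p_additive[cof] <- NA_real_
    scan$p_dominance[cof] <- NA_real_
    best <- pick_best(scan, candidates)
    if (is.null(best) || best$p > threshold) break
    cof <- c(cof, best$idx)
    step_found <- c(step_found, step)
    if (config$variance_strategy == "refit-per-step") {
      vc_current <- tryCatch(fit_vc(cof), error = function(e) vc_current)
      h2 <- heritabilities(vc_current)
      if (h2$h2_broad < 1e-6 && length(cof) < m) {
        warning("heritability collapsed to the boundary; stopping forward scan")
        break
      }
    }
  }

  # backward elimination: re-test each cofactor within the final model
  test_cofactor <- function(idx, others) {
    cofmat <- NULL
    if (length(others)) {
      cofmat <- cbind(Wa[, others, drop = FALSE],
                      Wb[, others[test_dom[others]], drop = FALSE])
    }
    single_marker_test(design, matrices, vc_current,
                       Wa[, idx], Wb[, idx], cofactors = cofmat)
  }
  repeat {
    if (!length(cof)) break
    ptab <- lapply(seq_along(cof), function(i) {
      test_cofactor(cof[i], cof[-i])
    })
    pmin_c <- vapply(ptab, function(r) {
      min(c(r$p_additive, r$p_dominance), na.rm = TRUE)
    }, numeric(1))
    worst <- which.max(pmin_c)
    if (pmin_c[worst] > threshold) {
      cof <- cof[-worst]
      step_found <- step_found[-worst]
    } else {
      break
    }
  }

  if (!length(cof)) {
    hits <- data.frame(snp_id = character(0), chrom = character(0),
                       pos = integer(0), effect_class = character(0),
                       p_additive = numeric(0), p_dominance = numeric(0),
                       step_found = integer(0), stringsAsFactors = FALSE)
  } else {
    rows <- lapply(seq_along(cof), function(i) {
      r <- test_cofactor(cof[i], cof[-i])
      sig_a <- !is.na(r$p_additive) && r$p_additive <= threshold
      sig_d <- !is.na(r$p_dominance) && r$p_dominance <= threshold
      cls <- if (sig_a && sig_d) "A+D" else if (sig_d) "D" else "A"
      data.frame(snp_id = meta$snp_id[cof[i]], chrom = meta$chrom[cof[i]],
                 pos = meta$pos[cof[i]], effect_class = cls,
                 p_additive = r$p_additive, p_dominance = r$p_dominance,
                 step_found = step_found[i], stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, rows)
  }
  attr(hits, "threshold") <- threshold
  attr(hits, "n_tests") <- n_tests
  class(hits) <- c("gwas_hits", class(hits))
  hits
}

#' Annotate GWAS hits with the nearest gene
#'
#' A SNP inside a gene interval is `within` (distance 0); otherwise the
#' closest interval end on either side is reported as `upstream` (SNP
#' before the gene start) or `downstream` (after the gene end) when within
#' 100 kb; hits farther than 100 kb from every gene carry the no-gene
#' marker (`gene_name = NA`, `relation = "none"`).
#'
#' @param hits a `gwas_hits` data frame (needs `chrom`, `pos`).
#' @param genes data frame with columns `chrom`, `start`, `end`, `name`;
#'   starts are 0-based half-open (BED convention), SNP positions 1-based.
#' @param max_distance annotation radius in base pairs (default 100,000).
#' @return `hits` with added columns `gene_name`, `relation`, `distance`.
#' @export
annotate_hits <- function(hits, genes, max_distance = 1e5) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)))
  if (any(genes$end < genes$start)) {
    stop("malformed gene interval: end < start")
  }
  genes$chrom <- as.character(genes$chrom)
  out <- hits
  out$gene_name <- NA_character_
  out$relation <- "none"
  out$distance <- NA_real_
  for (i in seq_len(nrow(hits))) {
    g <- genes[genes$chrom == as.character(hits$chrom[i]), , drop = FALSE]
    if (!nrow(g)) next
    pos <- hits$pos[i]
    inside <- pos > g$start & pos <= g$end # 0-based half-open interval
    if (any(inside)) {
      out$gene_name[i] <- g$name[which(inside)[1]]
      out$relation[i] <- "within"
      out$distance[i] <- 0
      next
    }
    dist_up <- (g$start + 1) - pos   # >0 when SNP is before the gene
    dist_down <- pos - g$end         # >0 when SNP is after the gene
    dist <- ifelse(dist_up > 0, dist_up, dist_down)
    k <- which.min(dist)
    if (dist[k] <= max_distance) {
      out$gene_name[i] <- g$name[k]
      out$relation[i] <- if (dist_up[k] > 0) "upstream" else "downstream"
      out$distance[i] <- dist[k]
    }
  }
  out
}
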
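#' Fixed-effect-corrected phenotypes
#'
#' Phenotype minus the ordinary-least-squares fixed-effect fit computed on
#' the full data; with an intercept in the design the result is centred.
#'
#' @param design a [trait_design()].
#' @return numeric vector of OLS residuals.
#' @export
corrected_phenotypes <- function(design) {
  stopifnot(inherits(design, "trait_design"))
  fit <- lm.fit(design$X, design$y)
  if (fit$rank < ncol(design$X)) stop("fixed-effects design is rank deficient")
  fit$residuals
}

#' Cross-validation plan
#'
#' Random partition of individuals into `k` approximately equal folds
#' (sizes differ by at most 1), repeated `repeats` times; reproducible
#' from the seed.
#'
#' @param ids character vector of individual ids.
#' @param k fold count (>= 2).
#' @param repeats number of independent repartitions.
#' @param seed integer seed.
#' @return list of class `cv_plan` with `ids`, `k`, `repeats`, `seed`, and
#'   `folds`: a `repeats x n` integer matrix of fold assignments.
#' @export
make_folds <- function(ids, k = 5L, repeats = 25L, seed = 1L) {
  n <- length(ids)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of individuals")
  set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  template <- rep(seq_len(k), times = sizes)
  folds <- t(vapply(seq_len(repeats),
                    function(r) template[order(sample.int(n))],
                    integer(n)))
  structure(list(ids = as.character(ids), k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 folds = folds),
            class = "cv_plan")
}

# GBLUP-type prediction of validation genetic values from a training fit:
# g_val = sum_i sigma_i K_i[val, train] V_train^-1 (y_train - X_train b_hat)
.gblup_predict <- function(design, matrices, vc, train, val,
                           target = c("breeding", "total")) {
  target <- match.arg(target)
  y <- design$y[train]
  X <- design$X[train, , drop = FALSE]
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE] # drop aliased levels
  k <- length(matrices)
  n_tr <- length(train)
  V <- vc$sigma_a2 * matrices[[1]]$values[train, train] + diag(vc$sigma_e2, n_tr)
  if (k == 2) V <- V + vc$sigma_d2 * matrices[[2]]$values[train, train]
  Vinv <- chol2inv(chol(V))
  XtVinv <- crossprod(X, Vinv)
  b_hat <- solve(XtVinv %*% X, XtVinv %*% y)
  resid <- drop(y - X %*% b_hat)
  w <- drop(Vinv %*% resid)
  pred <- vc$sigma_a2 * drop(matrices[[1]]$values[val, train, drop = FALSE] %*% w)
  if (target == "total" && k == 2) {
    pred <- pred + vc$sigma_d2 *
      drop(matrices[[2]]$values[val, train, drop = FALSE] %*% w)
  }
  pred
}

#' Repeated k-fold cross-validation of predictive ability
#'
#' For every repeat and fold, models are fitted on the training
#' individuals only and validation genetic values are predicted: GBLUP /
#' GBLUP-D through the relationship-matrix covariance between validation
#' and training individuals, BayesA / BayesAD through posterior-mean
#' marker effects.  Predictive ability is the correlation between the
#' predicted genetic values and the corrected phenotypes (full-data OLS
#' fixed-effect residuals by default) of the validation individuals.
#'
#' `G` and `D` are built once on all individuals (frequencies from the
#' full data) and sub-matrixed per fold.
#'
#' @param design a [trait_design()] for all individuals.
#' @param geno a [genotype_matrix()] for all individuals (used by the
#'   Bayes models and to build relationship matrices when not supplied).
#' @param models character subset of
#'   `c("GBLUP", "GBLUP-D", "BayesA", "BayesAD")`.
#' @param plan a [make_folds()] plan.
#' @param matrices optional precomputed list `list(G, D)`.
#' @param prediction_target `"breeding"` (additive genetic values, the
#'   default) or `"total"` (additive + dominance).
#' @param correction `"full-data"` (default) or `"training"`: whether the
#'   fixed-effect correction of validation phenotypes is estimated on all
#'   records or on the training records only.
#' @param bayes_hyper a [bayes_hyper()] used for the Bayes models; chains
#'   inside cross-validation default to 4000 sweeps / 1000 burn-in for
#'   desk-scale runtime.
#' @return list of class `cv_result`: `cells` (long data frame: model,
#'   repeat, fold, r) and `summary` (per model: mean and SD of r).
#' @export
cross_validate <- function(design, geno, models = c("GBLUP", "GBLUP-D"),
                           plan = make_folds(geno$individual_ids),
                           matrices = NULL,
                           prediction_target = c("breeding", "total"),
                           correction = c("full-data", "training"),
                           bayes_hyper = NULL) {
  prediction_target <- match.arg(prediction_target)
  correction <- match.arg(correction)
  models <- match.arg(models, c("GBLUP", "GBLUP-D", "BayesA", "BayesAD"),
                      several.ok = TRUE)
  n <- length(design$y)
  if (nrow(plan$folds) != plan$repeats || ncol(plan$folds) != n) {
    stop("plan does not match the number of individuals")
  }
  need_grm <- any(models %in% c("GBLUP", "GBLUP-D"))
  need_D <- "GBLUP-D" %in% models
  if (is.null(matrices) && need_grm) {
    G <- stabilize(build_G(geno), 1e-6)
    matrices <- list(G)
    if (need_D) matrices <- list(G, stabilize(build_D(geno), 1e-6))
  }
  need_bayes <- any(models %in% c("BayesA", "BayesAD"))
  if (need_bayes && is.null(bayes_hyper)) {
    bayes_hyper <- bayes_hyper(n_iterations = 4000L, burn_in = 1000L,
                               thinning = 5L, seed = plan$seed)
  }
  yc_full <- corrected_phenotypes(design)

  cells <- list()
  for (r in seq_len(plan$repeats)) {
    assign_r <- plan$folds[r, ]
    for (f in seq_len(plan$k)) {
      val <- which(assign_r == f)
      train <- which(assign_r != f)
      yc_val <- if (correction == "full-data") {
        yc_full[val]
      } else {
        Xtr <- design$X[train, , drop = FALSE]
        qrX <- qr(Xtr)
        keep <- qrX$pivot[seq_len(qrX$rank)]
        bhat <- qr.coef(qr(Xtr[, keep, drop = FALSE]), design$y[train])
        design$y[val] - drop(design$X[val, keep, drop = FALSE] %*% bhat)
      }
      if (sd(yc_val) == 0) {
        warning(sprintf("fold %d/%d has zero phenotypic variance; r set NA", r, f))
      }
      tr_design <- structure(
        list(y = design$y[train], X = design$X[train, , drop = FALSE],
             ids = design$ids[train]),
        class = "trait_design"
      )
      preds <- list()
      # a model failing on one training partition (e.g. REML non-convergence)
      # records a missing cell rather than aborting the whole validation
      try_fit <- function(expr) {
        tryCatch(expr, error = function(e) {
          warning(sprintf("fold %d/%d: %s", r, f, conditionMessage(e)))
          NULL
        })
      }
      if ("GBLUP" %in% models) {
        preds["GBLUP"] <- list(try_fit({
          vc <- reml_fit(tr_design_sub(tr_design), subset_rel(matrices[1], train))
          .gblup_predict(design, matrices[1], vc, train, val, prediction_target)
        }))
      }
      if ("GBLUP-D" %in% models) {
        preds["GBLUP-D"] <- list(try_fit({
          vc <- reml_fit(tr_design_sub(tr_design), subset_rel(matrices, train))
          .gblup_predict(design, matrices, vc, train, val, prediction_target)
        }))
      }
      if (need_bayes) {
        d_tr <- build_designs(subset_genotypes(geno, individuals = train))
        d_val <- build_designs(subset_genotypes(geno, individuals = val),
                               centers = d_tr)
        hy <- bayes_hyper
        hy$seed <- bayes_hyper$seed + 131L * r + f
        if ("BayesA" %in% models) {
          ch <- run_chain(tr_design_sub(tr_design), d_tr, hy, model = "bayesA")
          pv <- predict_genetic_values(ch, d_val)
          preds$BayesA <- pv[[prediction_target]]
        }
        if ("BayesAD" %in% models) {
          ch <- run_chain(tr_design_sub(tr_design), d_tr, hy, model = "bayesAD")
          pv <- predict_genetic_values(ch, d_val)
          preds$BayesAD <- pv[[prediction_target]]
        }
      }
      for (mod in names(preds)) {
        r_val <- if (!is.null(preds[[mod]]) && sd(yc_val) > 0 &&
                       sd(preds[[mod]]) > 0) {
          cor(preds[[mod]], yc_val)
        } else {
          NA_real_
        }
        cells[[length(cells) + 1L]] <- data.frame(
          model = mod, rep = r, fold = f, r = r_val, stringsAsFactors = FALSE
        )
      }
    }
  }
  cells <- do.call(rbind, cells)
  summary <- do.call(rbind, lapply(split(cells, cells$model), function(df) {
    data.frame(model = df$model[1], mean_r = mean(df$r, na.rm = TRUE),
               sd_r = sd(df$r, na.rm = TRUE), n_folds = nrow(df),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(cells = cells, summary = summary, plan = plan,
                 prediction_target = prediction_target),
            class = "cv_result")
}

# rebuild a trait_design after subsetting (drop aliased factor columns)
tr_design_sub <- function(design) {
  X <- design$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  structure(list(y = design$y, X = X, ids = design$ids),
            class = "trait_design")
}

# subset each relationship matrix in a list to the given individuals
subset_rel <- function(matrices, idx) {
  lapply(matrices, function(mat) {
    out <- mat
    out$values <- mat$values[idx, idx, drop = FALSE]
    out
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation (%d-fold x %d repeats, target = %s):\n",
              x$plan$k, x$plan$repeats, x$prediction_target))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
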
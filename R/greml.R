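#' Trait design: phenotype and fixed-effects matrix
#'
#' Builds the fixed-effects design matrix with an intercept and
#' reference-level dummy coding for factors.  One record per individual is
#' assumed (the individual-to-record incidence is the identity).
#'
#' @param y numeric phenotype vector.
#' @param covariates data frame of fixed-effect covariates (e.g. `year`,
#'   `sex` as factors, `entry_weight`, `fattening_days` numeric), or `NULL`
#'   for an intercept-only design.
#' @param formula right-hand-side formula selecting covariates; default uses
#'   every column.
#' @param ids optional individual identifiers carried through to outputs.
#' @return A list of class `trait_design` with `y`, `X`, and `ids`.
#' @export
trait_design <- function(y, covariates = NULL, formula = ~., ids = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("phenotypes must not contain NA")
  if (is.null(covariates)) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- droplevels(as.data.frame(covariates))
    if (nrow(covariates) != length(y)) stop("covariate rows != length(y)")
    X <- model.matrix(formula, data = covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("fixed-effects design is rank deficient; drop aliased covariates")
  }
  structure(list(y = y, X = X, ids = ids), class = "trait_design")
}

# restricted log-likelihood and derived quantities at sigma for
# V = sum_i sigma_i * V_i (last V_i the identity residual term)
.reml_eval <- function(y, X, Vlist, sigma) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(Vlist)) V <- V + sigma[i] * Vlist[[i]]
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(NULL)
  logdetV <- 2 * sum(log(diag(cholV)))
  Vinv <- chol2inv(cholV)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  cholXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cholXtVX)) return(NULL)
  logdetXtVX <- 2 * sum(log(diag(cholXtVX)))
  P <- Vinv - VinvX %*% chol2inv(cholXtVX) %*% t(VinvX)
  Py <- P %*% y
  yPy <- drop(crossprod(y, Py))
  logL <- -0.5 * (logdetV + logdetXtVX + yPy)
  list(logL = logL, P = P, Py = Py, Vinv = Vinv, VinvX = VinvX,
       XtVX = XtVX, cholXtVX = cholXtVX)
}

#' REML estimation of additive (and dominance) variance components
#'
#' Fits `y = X b + a + d + e` with `a ~ N(0, G sigma_a2)`,
#' `d ~ N(0, D sigma_d2)`, `e ~ N(0, I sigma_e2)` by restricted maximum
#' likelihood; the dominance term is dropped when only `G` is supplied
#' (GBLUP vs GBLUP-D).  Updates are average-information steps with
#' step-halving and an expectation-maximisation fallback whenever a step
#' would leave the feasible region or decrease the restricted likelihood,
#' so the likelihood ascends monotonically.  Components are constrained to
#' a small positive floor (`1e-8 * var(y)`); estimates at the floor are
#' reported as boundary solutions.
#'
#' @param design a [trait_design()].
#' @param matrices list of one or two `relationship_matrix` objects, e.g.
#'   `list(G)` or `list(G, D)`.
#' @param tol_logL convergence tolerance on the change in restricted
#'   log-likelihood.
#' @param tol_par convergence tolerance on the relative component change.
#' @param max_iter maximum number of iterations.
#' @param init optional starting values for the components
#'   (genetic terms first, residual last).
#' @return A list of class `variance_components` with `sigma_a2`,
#'   `sigma_d2` (`NA` when absent), `sigma_e2`, `logL`, `converged`,
#'   `n_iterations`, standard errors from the inverse average-information
#'   matrix, and the iteration trace.
#' @export
reml_fit <- function(design, matrices, tol_logL = 1e-6, tol_par = 1e-4,
                     max_iter = 200L, init = NULL) {
  stopifnot(inherits(design, "trait_design"))
  if (inherits(matrices, "relationship_matrix")) matrices <- list(matrices)
  k <- length(matrices)
  if (k < 1 || k > 2) stop("supply one (G) or two (G, D) relationship matrices")
  y <- design$y
  X <- design$X
  n <- length(y)
  for (mat in matrices) {
    if (!all(dim(mat$values) == n)) stop("relationship matrix dimension != n records")
  }
  Vlist <- c(lapply(matrices, `[[`, "values"), list(diag(1, n)))
  nc <- k + 1L
  vy <- var(y)
  lb <- 1e-8 * vy
  sigma <- if (is.null(init)) {
    r2 <- sum(lm.fit(X, y)$residuals^2) / (n - ncol(X))
    if (k == 1) c(0.5, 0.5) * r2 else c(0.4, 0.2, 0.4) * r2
  } else {
    pmax(as.numeric(init), lb)
  }
  ev <- .reml_eval(y, X, Vlist, sigma)
  if (is.null(ev)) stop("starting covariance matrix is not positive definite")
  trace <- data.frame(iter = 0L, logL = ev$logL,
                      t(setNames(sigma, paste0("sigma", seq_len(nc)))))
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  repeat {
    iter <- iter + 1L
    P <- ev$P
    Py <- ev$Py
    # score and average information
    trPV <- numeric(nc)
    yPVPy <- numeric(nc)
    Q <- matrix(0, n, nc)
    for (i in seq_len(nc)) {
      Vi <- Vlist[[i]]
      trPV[i] <- sum(P * Vi) # tr(P Vi), both symmetric
      Q[, i] <- Vi %*% Py
      yPVPy[i] <- drop(crossprod(Py, Q[, i]))
    }
    score <- -0.5 * (trPV - yPVPy)
    AI <- 0.5 * crossprod(Q, P %*% Q)
    # active set: components stuck at the lower bound with a negative score
    # are held there so the AI step can converge quadratically in the rest
    free <- sigma > 1.5 * lb | score > 0
    if (!any(free)) free[which.max(score)] <- TRUE
    step <- rep(0, nc)
    step[free] <- tryCatch(
      solve(AI[free, free, drop = FALSE], score[free]),
      error = function(e) rep(NA_real_, sum(free))
    )
    accepted <- FALSE
    if (all(is.finite(step))) {
      h <- 1
      for (try in 1:8) { # step halving keeps the ascent monotone
        cand <- pmax(sigma + h * step, lb)
        cand[!free] <- lb
        ev_cand <- .reml_eval(y, X, Vlist, cand)
        if (!is.null(ev_cand) && ev_cand$logL >= ev$logL - 1e-10) {
          accepted <- TRUE
          break
        }
        h <- h / 2
      }
    }
    if (!accepted) {
      # EM-REML update (guaranteed ascent): sigma_i += sigma_i^2/n * (y'P Vi P y - tr(P Vi))
      cand <- pmax(sigma + sigma^2 / n * (yPVPy - trPV), lb)
      ev_cand <- .reml_eval(y, X, Vlist, cand)
      if (is.null(ev_cand)) {
        stop("REML failed: covariance not positive definite during EM fallback")
      }
    }
    dlogL <- ev_cand$logL - ev$logL
    # components pinned at the boundary are excluded from the relative-change
    # criterion (they oscillate harmlessly at numerical-zero scale)
    active <- cand > 100 * lb
    dpar <- if (any(active)) {
      max(abs(cand[active] - sigma[active]) / pmax(abs(sigma[active]), lb))
    } else {
      0
    }
    sigma <- cand
    ev <- ev_cand
    trace <- rbind(trace, data.frame(iter = iter, logL = ev$logL,
                                     t(setNames(sigma, paste0("sigma", seq_len(nc))))))
    if (abs(dlogL) < tol_logL && dpar < tol_par) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    cond <- simpleError(sprintf("REML did not converge in %d iterations", max_iter))
    cond$trace <- trace
    stop(cond)
  }
  se <- rep(NA_real_, nc)
  covAI <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(covAI)) se <- sqrt(pmax(diag(covAI), 0))
  structure(
    list(
      sigma_a2 = sigma[1],
      sigma_d2 = if (k == 2) sigma[2] else NA_real_,
      sigma_e2 = sigma[nc],
      se = setNames(se, c("sigma_a2", if (k == 2) "sigma_d2", "sigma_e2")),
      logL = ev$logL,
      converged = converged,
      n_iterations = iter,
      boundary = sigma <= lb * (1 + 1e-9),
      model = if (k == 2) "GBLUP-D" else "GBLUP",
      trace = trace
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("%s REML fit (%d iterations, logL = %.4f)\n",
              x$model, x$n_iterations, x$logL))
  cat(sprintf("  sigma_a2 = %.6g", x$sigma_a2))
  if (!is.na(x$sigma_d2)) cat(sprintf("  sigma_d2 = %.6g", x$sigma_d2))
  cat(sprintf("  sigma_e2 = %.6g\n", x$sigma_e2))
  invisible(x)
}

#' Heritability ratios from variance components
#'
#' Narrow-sense heritability `sigma_a2 / sigma_p2`, dominance ratio
#' `sigma_d2 / sigma_p2`, their sum (broad-sense, additive + dominance),
#' and the dominance share of the genetic variance
#' `sigma_d2 / (sigma_a2 + sigma_d2)`, where
#' `sigma_p2 = sigma_a2 + sigma_d2 + sigma_e2`.
#'
#' @param vc a `variance_components` object, or a numeric vector/list with
#'   elements `sigma_a2`, `sigma_d2`, `sigma_e2` (`sigma_d2` may be `NA`
#'   or absent for an additive-only model).
#' @return list of class `heritability_estimates` with `h2_narrow`,
#'   `h2_dominance`, `h2_broad`, `dominance_to_genetic`.
#' @export
heritabilities <- function(vc) {
  if (is.numeric(vc) && is.null(names(vc))) {
    stopifnot(length(vc) %in% c(2L, 3L))
    vc <- if (length(vc) == 3L) {
      list(sigma_a2 = vc[1], sigma_d2 = vc[2], sigma_e2 = vc[3])
    } else {
      list(sigma_a2 = vc[1], sigma_d2 = NA_real_, sigma_e2 = vc[2])
    }
  }
  sa <- vc$sigma_a2
  sd2 <- if (is.null(vc$sigma_d2) || is.na(vc$sigma_d2)) 0 else vc$sigma_d2
  se2 <- vc$sigma_e2
  if (any(c(sa, sd2, se2) < 0)) stop("variance components must be nonnegative")
  tot <- sa + sd2 + se2
  if (tot <= 0) stop("total variance must be positive")
  structure(
    list(
      h2_narrow = sa / tot,
      h2_dominance = sd2 / tot,
      h2_broad = (sa + sd2) / tot,
      dominance_to_genetic = if (sa + sd2 > 0) sd2 / (sa + sd2) else 0
    ),
    class = "heritability_estimates"
  )
}

#' @export
print.heritability_estimates <- function(x, ...) {
  cat(sprintf("h2_narrow = %.3f  h2_dominance = %.3f  h2_broad = %.3f  d/(a+d) = %.3f\n",
              x$h2_narrow, x$h2_dominance, x$h2_broad, x$dominance_to_genetic))
  invisible(x)
}

#' Solve the mixed-model equations for fixed effects and BLUPs
#'
#' Henderson mixed-model equations for `y = X b + a + d + e` at the given
#' variance components; the dominance block is present only when a
#' dominance matrix is supplied.
#'
#' @inheritParams reml_fit
#' @param vc a `variance_components` object (components for the included
#'   terms must be strictly positive).
#' @param ridge added to `G`/`D` before inversion when they are singular.
#' @return list of class `blup_solution` with `b_hat`, `a_hat`, `d_hat`
#'   (`NULL` when no dominance term).
#' @export
blup_solve <- function(design, matrices, vc, ridge = 1e-8) {
  stopifnot(inherits(design, "trait_design"))
  if (inherits(matrices, "relationship_matrix")) matrices <- list(matrices)
  k <- length(matrices)
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  comp <- c(vc$sigma_a2, if (k == 2) vc$sigma_d2)
  if (any(comp <= 0)) stop("variance components of included random terms must be > 0")
  inv_rel <- lapply(seq_len(k), function(i) {
    Vi <- matrices[[i]]$values
    Vi_inv <- tryCatch(chol2inv(chol(Vi)), error = function(e) NULL)
    if (is.null(Vi_inv)) {
      Vi_inv <- tryCatch(chol2inv(chol(Vi + diag(ridge, n))),
                         error = function(e) NULL)
      if (is.null(Vi_inv)) {
        stop("singular relationship matrix; increase ridge via stabilize()")
      }
    }
    Vi_inv
  })
  lambda <- vc$sigma_e2 / comp
  # coefficient matrix [X'X X' X'; X I+l1*Ginv I; X I I+l2*Dinv]
  dims <- p + k * n
  C <- matrix(0, dims, dims)
  rhs <- numeric(dims)
  C[1:p, 1:p] <- crossprod(X)
  rhs[1:p] <- crossprod(X, y)
  I_n <- diag(1, n)
  for (i in seq_len(k)) {
    ri <- p + (i - 1) * n + seq_len(n)
    C[1:p, ri] <- t(X)
    C[ri, 1:p] <- X
    rhs[ri] <- y
    for (j in seq_len(k)) {
      cj <- p + (j - 1) * n + seq_len(n)
      C[ri, cj] <- I_n
    }
    C[ri, ri] <- I_n + lambda[i] * inv_rel[[i]]
  }
  # Jacobi scaling: the blocks mix scales badly when a lambda is large
  s <- 1 / sqrt(pmax(diag(C), .Machine$double.eps))
  Cs <- C * tcrossprod(s)
  sol <- tryCatch(s * solve(Cs, s * rhs), error = function(e) {
    stop("singular mixed-model coefficient matrix; stabilise G/D with a ridge")
  })
  structure(
    list(
      b_hat = setNames(sol[1:p], colnames(X)),
      a_hat = sol[p + seq_len(n)],
      d_hat = if (k == 2) sol[p + n + seq_len(n)] else NULL
    ),
    class = "blup_solution"
  )
}

#' Likelihood-ratio test of the dominance component
#'
#' `chi2 = max(0, 2 (logL_full - logL_reduced))` comparing GBLUP-D against
#' GBLUP.  Because a single variance component is tested at its boundary,
#' the p-value uses the `0.5 chi2_0 + 0.5 chi2_1` mixture; the plain
#' 1-df chi-square p-value is also reported.
#'
#' @param logL_reduced,logL_full restricted log-likelihoods of the nested
#'   (additive-only) and full (additive + dominance) models.
#' @return list of class `lrt_result` with `chi2`, `p_value` (mixture),
#'   `p_value_chi2_1df`, `df_nominal`.
#' @export
likelihood_ratio_test <- function(logL_reduced, logL_full) {
  if (!is.finite(logL_reduced) || !is.finite(logL_full)) {
    stop("log-likelihoods must be finite")
  }
  chi2 <- 2 * (logL_full - logL_reduced)
  if (chi2 < 0) {
    warning("logL_full < logL_reduced (optimizer noise); chi2 clamped to 0")
    chi2 <- 0
  }
  structure(
    list(
      chi2 = chi2,
      p_value = 0.5 * pchisq(chi2, df = 1, lower.tail = FALSE),
      p_value_chi2_1df = pchisq(chi2, df = 1, lower.tail = FALSE),
      df_nominal = 1L
    ),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.4f, boundary-mixture p = %.4g (plain 1-df p = %.4g)\n",
              x$chi2, x$p_value, x$p_value_chi2_1df))
  invisible(x)
}
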
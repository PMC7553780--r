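# Generalized weighted linear regression machinery shared by the IVW and
# MR-Egger estimators. The weighting matrix is Omega = D rho D with
# D = diag(outcome SEs) and rho the signed LD correlation matrix.

make_omega <- function(sy, rho) outer(sy, sy) * rho

# Cholesky of Omega with the documented ridge regularization: if the
# smallest eigenvalue is below 1e-8 times the largest, add
# 1e-8 * trace/J to the diagonal (near-duplicate variants in gene regions
# make Omega numerically singular).
omega_chol <- function(omega, rho, variants) {
  J <- nrow(omega)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev)) {
    warning("near-singular weighting matrix; adding ridge regularization")
    omega <- omega + diag(1e-8 * sum(diag(omega)) / J, J)
  }
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) {
    r2 <- rho^2; diag(r2) <- 0
    ij <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "weighting matrix singular after regularization (worst variant pair: %s, %s)",
      variants[ij[1L]], variants[ij[2L]]))
  }
  ch
}

# GLS fit of by on design X with covariance Omega (via its Cholesky factor).
# Returns coefficients, their fixed-effect covariance, and the residual
# quadratic form Q = r' Omega^-1 r.
gls_fit <- function(X, by, ch) {
  U <- backsolve(ch, X, transpose = TRUE)
  u <- backsolve(ch, by, transpose = TRUE)
  XtX <- crossprod(U)
  cov_fe <- solve(XtX)
  coefs <- drop(cov_fe %*% crossprod(U, u))
  Q <- sum((u - U %*% coefs)^2)
  list(coef = coefs, cov = cov_fe, Q = Q)
}

re_factor <- function(Q, df, random_effects) {
  if (!random_effects || df < 1) return(1)
  max(1, sqrt(Q / df))
}

#' Inverse-variance weighted estimate accounting for correlated variants
#'
#' Generalized weighted linear regression of the outcome associations on
#' the exposure associations without intercept, with weighting matrix
#' `Omega = diag(sy) %*% rho %*% diag(sy)`. With `rho = I` this is the
#' textbook uncorrelated IVW estimate; with a single variant it reduces to
#' the Wald ratio. Under the multiplicative random-effects model the
#' standard error is inflated by `max(1, sqrt(Q / (J - 1)))`, so it never
#' beats the fixed-effect precision.
#'
#' @param data a [harmonized_data] object with one exposure (for several
#'   exposures use [mvmr_ivw()] or select with `exposure`).
#' @param random_effects logical; apply multiplicative random-effects SE
#'   scaling (default `TRUE`).
#' @param exposure exposure column (index or name) to use.
#' @return An [mr_estimate] with heterogeneity statistics (J >= 2).
#' @export
ivw_correlated <- function(data, random_effects = TRUE, exposure = 1L) {
  stopifnot(inherits(data, "harmonized_data"))
  bx <- data$bx[, exposure]
  by <- data$by; sy <- data$sy
  J <- length(by)
  stopifnot(J >= 1L)
  ch <- omega_chol(make_omega(sy, data$rho), data$rho, data$variants)
  fit <- gls_fit(matrix(bx, ncol = 1L), by, ch)
  df <- J - 1L
  scl <- re_factor(fit$Q, df, random_effects)
  het <- if (J >= 2L) het_stats(fit$Q, df) else
    list(Q = NA_real_, I2 = NA_real_, p = NA_real_)
  mr_estimate(if (random_effects) "IVW (random-effects)" else "IVW (fixed-effect)",
              beta = fit$coef[1L], se = sqrt(fit$cov[1L, 1L]) * scl,
              exposure = if (is.numeric(exposure)) data$exposures[exposure] else exposure,
              outcome = data$outcome, n_variants = J,
              Q = het$Q, df_Q = if (J >= 2L) df else NA_real_, I2 = het$I2,
              p_het = het$p, re_scale = scl)
}

#' Multivariable inverse-variance weighted estimates
#'
#' Joint generalized weighted regression of the outcome associations on all
#' exposure association columns without intercept, giving each lipid
#' fraction's direct effect conditional on the others. Reduces exactly to
#' [ivw_correlated()] when there is a single exposure. Random-effects SE
#' scaling uses the residual degrees of freedom `J - K`.
#'
#' @inheritParams ivw_correlated
#' @return A named list of [mr_estimate] objects, one per exposure, each
#'   annotated with the shared heterogeneity statistics.
#' @export
mvmr_ivw <- function(data, random_effects = TRUE) {
  stopifnot(inherits(data, "harmonized_data"))
  B <- data$bx
  J <- nrow(B); K <- ncol(B)
  if (J <= K) stop("need more variants than exposures (J > K)")
  qrB <- qr(B)
  if (qrB$rank < K) {
    bad <- data$exposures[setdiff(seq_len(K), qrB$pivot[seq_len(qrB$rank)])]
    stop("exposure associations are collinear: ", paste(bad, collapse = ", "))
  }
  ch <- omega_chol(make_omega(data$sy, data$rho), data$rho, data$variants)
  fit <- gls_fit(B, data$by, ch)
  df <- J - K
  scl <- re_factor(fit$Q, df, random_effects)
  het <- het_stats(fit$Q, df)
  ests <- lapply(seq_len(K), function(k)
    mr_estimate(if (random_effects) "MVMR-IVW (random-effects)" else "MVMR-IVW (fixed-effect)",
                beta = fit$coef[k], se = sqrt(fit$cov[k, k]) * scl,
                exposure = data$exposures[k], outcome = data$outcome,
                n_variants = J, Q = het$Q, df_Q = df, I2 = het$I2,
                p_het = het$p, re_scale = scl))
  names(ests) <- data$exposures
  ests
}
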
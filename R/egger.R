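# MR-Egger: generalized weighted regression of outcome on exposure
# associations with a free intercept. The intercept estimates average
# directional pleiotropy; the slope is the pleiotropy-adjusted causal
# estimate. Variants are first oriented so the exposure of interest has
# non-negative associations; orienting a variant flips the signs of its
# exposure and outcome betas and of its row/column of the signed LD matrix,
# so results are invariant to the input orientation.

orient_positive <- function(data, exposure = 1L) {
  s <- ifelse(data$bx[, exposure] < 0, -1, 1)
  data$bx <- data$bx * s
  data$by <- data$by * s
  data$rho <- data$rho * outer(s, s)
  data
}

egger_gls <- function(data, columns, random_effects) {
  J <- nrow(data$bx)
  X <- cbind(intercept = 1, data$bx[, columns, drop = FALSE])
  ch <- omega_chol(make_omega(data$sy, data$rho), data$rho, data$variants)
  fit <- gls_fit(X, data$by, ch)
  df <- J - ncol(X)
  scl <- re_factor(fit$Q, df, random_effects)
  het <- het_stats(fit$Q, df)
  list(fit = fit, df = df, scl = scl, het = het)
}

#' MR-Egger regression (univariable)
#'
#' @param data a [harmonized_data] object; the signed LD matrix is used in
#'   the weighting, so correlated variants are supported.
#' @param exposure exposure column (index or name) of interest.
#' @param random_effects multiplicative random-effects SE scaling with
#'   residual degrees of freedom `J - 2`.
#' @return An [mr_estimate] whose `intercept*` fields carry the average
#'   directional pleiotropy estimate. A near-zero spread of the exposure
#'   associations is flagged (`flags$unstable`) since the slope is then
#'   unidentified.
#' @export
mr_egger <- function(data, exposure = 1L, random_effects = TRUE) {
  stopifnot(inherits(data, "harmonized_data"))
  J <- nrow(data$bx)
  if (J < 3L) stop("MR-Egger needs at least 3 variants")
  data <- orient_positive(data, exposure)
  bx <- data$bx[, exposure]
  unstable <- sd(bx) < 1e-8 * max(mean(abs(bx)), .Machine$double.eps)
  if (unstable)
    warning("exposure associations have near-zero spread; MR-Egger slope is unstable")
  e <- egger_gls(data, exposure, random_effects)
  ise <- sqrt(e$fit$cov[1L, 1L]) * e$scl
  mr_estimate("MR-Egger", beta = e$fit$coef[2L],
              se = sqrt(e$fit$cov[2L, 2L]) * e$scl,
              exposure = if (is.numeric(exposure)) data$exposures[exposure] else exposure,
              outcome = data$outcome, n_variants = J,
              Q = e$het$Q, df_Q = e$df, I2 = e$het$I2, p_het = e$het$p,
              re_scale = e$scl,
              intercept = e$fit$coef[1L], intercept_se = ise,
              intercept_p = 2 * pnorm(-abs(e$fit$coef[1L] / ise)),
              flags = list(unstable = unstable))
}

#' Multivariable MR-Egger regression
#'
#' Adds all exposure columns plus a free intercept; variants are oriented
#' so that the associations with `orient_by` (default: the first exposure)
#' are non-negative.
#'
#' @inheritParams mr_egger
#' @param orient_by exposure used for sign orientation.
#' @return A named list of [mr_estimate] objects (one per exposure), each
#'   carrying the shared intercept and heterogeneity statistics.
#' @export
mvmr_egger <- function(data, orient_by = 1L, random_effects = TRUE) {
  stopifnot(inherits(data, "harmonized_data"))
  J <- nrow(data$bx); K <- ncol(data$bx)
  if (J < K + 2L) stop("multivariable MR-Egger needs J >= K + 2 variants")
  data <- orient_positive(data, orient_by)
  e <- egger_gls(data, seq_len(K), random_effects)
  ise <- sqrt(e$fit$cov[1L, 1L]) * e$scl
  ests <- lapply(seq_len(K), function(k)
    mr_estimate("MVMR-Egger", beta = e$fit$coef[k + 1L],
                se = sqrt(e$fit$cov[k + 1L, k + 1L]) * e$scl,
                exposure = data$exposures[k], outcome = data$outcome,
                n_variants = J, Q = e$het$Q, df_Q = e$df, I2 = e$het$I2,
                p_het = e$het$p, re_scale = e$scl,
                intercept = e$fit$coef[1L], intercept_se = ise,
                intercept_p = 2 * pnorm(-abs(e$fit$coef[1L] / ise))))
  names(ests) <- data$exposures
  ests
}
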
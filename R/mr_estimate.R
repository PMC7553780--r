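#' Causal-effect estimate container
#'
#' All estimators in the package return an `mr_estimate`: a causal log
#' odds ratio per one standard deviation increase in the exposure, with its
#' standard error, normal 95% confidence interval, two-sided p-value, the
#' odds-ratio scale equivalents, and (where computed) heterogeneity
#' statistics and the MR-Egger intercept.
#'
#' @param method character label, e.g. `"IVW"`, `"MVMR-IVW"`, `"MR-Egger"`.
#' @param beta causal estimate on the log-OR scale per 1 SD exposure.
#' @param se standard error of `beta` (after any random-effects scaling).
#' @param exposure,outcome trait labels.
#' @param n_variants number of variants used.
#' @param p two-sided p-value; computed from `beta/se` when `NULL`.
#' @param Q,df_Q,I2,p_het Cochran's Q heterogeneity statistic, its degrees of
#'   freedom, Higgins' I-squared (percent) and the chi-square p-value.
#' @param re_scale multiplicative random-effects SE scale factor (>= 1).
#' @param intercept,intercept_se,intercept_p MR-Egger intercept terms.
#' @param flags named list of fit diagnostics (e.g. `unstable`).
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, exposure = NA_character_,
                        outcome = NA_character_, n_variants = NA_integer_,
                        p = NULL, Q = NA_real_, df_Q = NA_real_,
                        I2 = NA_real_, p_het = NA_real_, re_scale = 1,
                        intercept = NA_real_, intercept_se = NA_real_,
                        intercept_p = NA_real_, flags = list()) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.numeric(se), se > 0)
  z <- qnorm(0.975)
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  est <- list(
    method = method, exposure = exposure, outcome = outcome,
    n_variants = as.integer(n_variants),
    beta = beta, se = se,
    ci_lower = beta - z * se, ci_upper = beta + z * se,
    or = exp(beta), or_lower = exp(beta - z * se),
    or_upper = exp(beta + z * se),
    p = p, Q = Q, df_Q = df_Q, I2 = I2, p_het = p_het,
    re_scale = re_scale,
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = intercept_p, flags = flags)
  class(est) <- "mr_estimate"
  est
}

#' Build an estimate from a printed odds ratio and confidence interval
#'
#' Reconstructs the log-scale estimate from an OR and its 95% CI as printed
#' in a results table (SE from the CI width under normality).
#'
#' @param or,lcl,ucl odds ratio and 95% confidence limits.
#' @param p optional two-sided p-value to carry along.
#' @inheritParams mr_estimate
#' @export
mr_estimate_from_or <- function(or, lcl, ucl, p = NULL, method = "reported",
                                exposure = NA, outcome = NA) {
  stopifnot(or > 0, lcl > 0, ucl > lcl)
  se <- (log(ucl) - log(lcl)) / (2 * qnorm(0.975))
  est <- mr_estimate(method, log(or), se, exposure, outcome, p = p)
  # preserve the printed CI exactly (it may have been rounded upstream)
  est$ci_lower <- log(lcl); est$ci_upper <- log(ucl)
  est$or_lower <- lcl; est$or_upper <- ucl
  est
}

#' Re-express an estimate per one SD *decrease* in the exposure
#'
#' Negates the log-scale estimate: the OR becomes its reciprocal and the
#' confidence bounds are reciprocated and swapped. The p-value is unchanged.
#' Applying it twice returns the original estimate.
#'
#' @param est an [mr_estimate].
#' @return The inverted `mr_estimate`.
#' @export
invert_direction <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  out <- est
  out$beta <- -est$beta
  out$ci_lower <- -est$ci_upper
  out$ci_upper <- -est$ci_lower
  out$or <- 1 / est$or
  out$or_lower <- 1 / est$or_upper
  out$or_upper <- 1 / est$or_lower
  if (!is.na(est$intercept)) out$intercept <- -est$intercept
  out
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s estimate (%s -> %s), %s variants\n", x$method,
              x$exposure, x$outcome,
              ifelse(is.na(x$n_variants), "?", x$n_variants)))
  cat(sprintf("  beta = %.*f (SE %.*f), OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              digits, x$beta, digits, x$se, x$or, x$or_lower, x$or_upper, x$p))
  if (!is.na(x$Q))
    cat(sprintf("  Q = %.2f on %g df (p = %.3g), I2 = %.1f%%, RE scale %.2f\n",
                x$Q, x$df_Q, x$p_het, x$I2, x$re_scale))
  if (!is.na(x$intercept))
    cat(sprintf("  Egger intercept = %.*g (SE %.*g), p = %.3g\n",
                digits, x$intercept, digits, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, exposure = x$exposure, outcome = x$outcome,
             n_variants = x$n_variants, beta = x$beta, se = x$se,
             lcl = x$ci_lower, ucl = x$ci_upper, or = x$or,
             or_lcl = x$or_lower, or_ucl = x$or_upper, p = x$p,
             Q = x$Q, I2 = x$I2, p_het = x$p_het,
             intercept = x$intercept, intercept_se = x$intercept_se,
             stringsAsFactors = FALSE)
}

#' Bind a list of estimates into a tidy table
#'
#' @param ests a list of [mr_estimate] objects (a single estimate is
#'   accepted).
#' @return A data.frame with one row per estimate.
#' @export
estimates_table <- function(ests) {
  if (inherits(ests, "mr_estimate")) ests <- list(ests)
  do.call(rbind, lapply(ests, as.data.frame))
}

#' Format an odds ratio with its confidence interval for presentation
#'
#' Rounding to two decimals happens only here; internal computations carry
#' full precision.
#'
#' @param est an [mr_estimate].
#' @export
format_or <- function(est) {
  sprintf("%.2f (%.2f-%.2f)", est$or, est$or_lower, est$or_upper)
}
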
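het_stats <- function(Q, df) {
  list(Q = Q,
       I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
       p = if (df >= 1) pchisq(Q, df, lower.tail = FALSE) else NA_real_)
}

#' Cochran's Q and Higgins' I-squared heterogeneity statistics
#'
#' For uncorrelated variants this is the classic
#' `Q = sum(w_j (r_j - beta)^2)` over per-variant ratio estimates
#' `r_j = by_j / bx_j` with weights `w_j = bx_j^2 / sy_j^2`; with a
#' non-identity LD matrix the generalized quadratic form
#' `r' Omega^-1 r` on the fit residuals is used (the two coincide at
#' `rho = I`). `I2 = max(0, (Q - df)/Q) * 100`; the p-value is from a
#' chi-square distribution with `df = J - K` degrees of freedom.
#'
#' @param data a [harmonized_data] object.
#' @param beta fitted causal effect(s): a scalar for a univariable fit or a
#'   vector of length K for a multivariable fit.
#' @return A list with elements `Q`, `I2` (percent), `p_het` and `df`.
#' @export
cochran_q <- function(data, beta) {
  stopifnot(inherits(data, "harmonized_data"))
  J <- nrow(data$bx)
  K <- length(beta)
  stopifnot(J >= 2L, K <= ncol(data$bx))
  resid <- data$by - drop(data$bx[, seq_len(K), drop = FALSE] %*% beta)
  ch <- omega_chol(make_omega(data$sy, data$rho), data$rho, data$variants)
  u <- backsolve(ch, resid, transpose = TRUE)
  Q <- sum(u^2)
  df <- J - K
  h <- het_stats(Q, df)
  list(Q = Q, I2 = h$I2, p_het = h$p, df = df)
}
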
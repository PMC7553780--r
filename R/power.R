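#' Power of a two-sample MR analysis with a binary outcome
#'
#' Standard asymptotic approximation: the causal log-OR estimate is
#' normal with standard error `1 / sqrt(n r2 K (1-K))` where `n` is the
#' outcome sample size, `r2` the variance of the exposure explained by the
#' instrument, and `K` the case fraction (the `K(1-K)` term is the
#' logistic information at the margin). The two-sided power at level
#' `alpha` is
#' `pnorm(|b| s - z) + pnorm(-|b| s - z)` with `s = sqrt(n r2 K (1-K))`
#' and `z = qnorm(1 - alpha/2)`, which equals `alpha` exactly at OR = 1.
#'
#' @param or odds ratio per SD of the exposure (vectorized).
#' @param n outcome sample size.
#' @param r2 variance of the exposure explained by the instrument, in
#'   (0, 1).
#' @param case_fraction case fraction K in (0, 1).
#' @param alpha two-sided significance level.
#' @return Power in (0, 1), vectorized over the inputs.
#' @export
mr_power <- function(or, n, r2, case_fraction, alpha = 0.05) {
  stopifnot(all(or > 0), all(n >= 1), all(r2 > 0), all(r2 < 1),
            all(case_fraction > 0), all(case_fraction < 1),
            alpha > 0, alpha < 1)
  b <- abs(log(or))
  s <- sqrt(n * r2 * case_fraction * (1 - case_fraction))
  z <- qnorm(1 - alpha / 2)
  pnorm(b * s - z) + pnorm(-b * s - z)
}

#' Minimum detectable odds ratio at a target power
#'
#' Inverts [mr_power()] for the log odds ratio: Newton iteration from the
#' closed-form one-sided start `|log OR| = (z + qnorm(target)) / s`, so
#' the round trip `mr_power(detectable_or(...))` reproduces the target
#' power to near machine precision. Returns the symmetric pair of
#' detectable ORs above and below 1.
#'
#' @inheritParams mr_power
#' @param target_power desired power, in `(alpha, 1)`.
#' @return Named vector `c(lower = exp(-|b|), upper = exp(|b|))`.
#' @export
detectable_or <- function(n, r2, case_fraction, target_power = 0.8,
                          alpha = 0.05) {
  stopifnot(target_power > alpha, target_power < 1)
  s <- sqrt(n * r2 * case_fraction * (1 - case_fraction))
  z <- qnorm(1 - alpha / 2)
  x <- z + qnorm(target_power)  # one-sided closed-form start, in units of b*s
  for (i in 1:50) {
    f <- pnorm(x - z) + pnorm(-x - z) - target_power
    g <- dnorm(x - z) - dnorm(x + z)
    step <- f / g
    x <- x - step
    if (abs(step) < 1e-14) break
  }
  b <- x / s
  c(lower = exp(-b), upper = exp(b))
}

#' Detectable-OR grid over outcome case counts
#'
#' Tabulates the OR detectable at a target power for each outcome (given
#' its case count) and each instrument strength, the shape of a power
#' figure comparing gene-specific and polygenic analyses.
#'
#' @param case_counts named vector of case counts per outcome.
#' @param n total sample size.
#' @param r2 one or more instrument variance-explained values.
#' @inheritParams detectable_or
#' @return data.frame with one row per outcome x r2.
#' @export
detectable_or_grid <- function(case_counts, n, r2, target_power = 0.8,
                               alpha = 0.05) {
  rows <- lapply(names(case_counts), function(lbl) {
    K <- case_counts[[lbl]] / n
    do.call(rbind, lapply(r2, function(r) {
      ors <- detectable_or(n, r, K, target_power, alpha)
      data.frame(outcome = lbl, cases = case_counts[[lbl]],
                 case_fraction = K, r2 = r,
                 or_lower = ors[["lower"]], or_upper = ors[["upper"]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
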
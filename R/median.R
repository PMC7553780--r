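# Weighted median estimator: the per-variant Wald ratios are ordered and
# the estimate is read off at cumulative weight one half, interpolating
# linearly between the midpoints of the cumulative weight bands.

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(r[1L])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR estimate
#'
#' Per-variant ratio estimates `r_j = by_j / bx_j` with inverse-variance
#' weights `w_j = bx_j^2 / sy_j^2` (normalized to sum one); the estimate is
#' the linear interpolation of the ordered ratios at cumulative weight 0.5
#' using band midpoints. Consistent when at least half the weight comes
#' from valid instruments. The standard error is a parametric bootstrap:
#' `n_boot` resamples of (bx, by) from their normal sampling distributions.
#'
#' Variants must be (near) uncorrelated: prune first with
#' [prune_correlated()].
#'
#' @param data a [harmonized_data] object with uncorrelated variants.
#' @param exposure exposure column of interest.
#' @param n_boot bootstrap resamples for the SE (default 1000).
#' @param seed RNG seed for the bootstrap, recorded in the output flags.
#' @return An [mr_estimate]; `flags$boot_seed` records the seed.
#' @export
weighted_median <- function(data, exposure = 1L, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(data, "harmonized_data"))
  J <- nrow(data$bx)
  if (J < 3L) stop("weighted median needs at least 3 variants")
  offdiag <- data$rho; diag(offdiag) <- 0
  if (max(offdiag^2) >= 0.4)
    warning("strongly correlated variants present; prune with prune_correlated() first")
  bx <- data$bx[, exposure]; sx <- data$sx[, exposure]
  by <- data$by; sy <- data$sy
  if (any(bx == 0)) stop("zero exposure association for variant(s): ",
                         paste(data$variants[bx == 0], collapse = ", "))
  est <- weighted_median_point(by / bx, bx^2 / sy^2)
  boots <- with_seed(seed, {
    BX <- matrix(rnorm(J * n_boot, bx, sx), nrow = J)
    BY <- matrix(rnorm(J * n_boot, by, sy), nrow = J)
    vapply(seq_len(n_boot), function(b) {
      bxb <- BX[, b]
      bxb[bxb == 0] <- .Machine$double.eps
      weighted_median_point(BY[, b] / bxb, bxb^2 / sy^2)
    }, numeric(1L))
  })
  se <- sd(boots)
  mr_estimate("Weighted median", beta = est, se = se,
              exposure = if (is.numeric(exposure)) data$exposures[exposure] else exposure,
              outcome = data$outcome, n_variants = J,
              flags = list(boot_seed = seed, n_boot = n_boot))
}
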
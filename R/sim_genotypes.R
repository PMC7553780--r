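# Haplotype-threshold genotype model: each haplotype's alleles come from a
# latent Gaussian AR(1) process (correlation ld_decay^|i-j|) thresholded at
# each variant's MAF quantile; a dosage is the sum of two independent
# haplotypes. The implied signed dosage correlation matrix is available in
# closed form (bivariate-normal orthant probabilities), so estimators can
# be handed the exact LD matrix rather than an estimate.

#' Simulate genotype dosages
#'
#' @param config a [sim_config].
#' @param n number of individuals (default: the exposure sample size).
#' @param seed RNG seed (default: the config seed).
#' @return An n x J integer dosage matrix (0/1/2) with variant ids as
#'   column names and the allele-frequency vector in `attr(, "maf")`.
#' @export
simulate_genotypes <- function(config, n = config$n_exposure_sample,
                               seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  a <- config$ld_decay
  if (a < 0 || a >= 1) stop("ld_decay must lie in [0, 1)")
  J <- config$n_variants
  thr <- qnorm(config$maf)
  one_haplotype <- function() {
    Z <- matrix(rnorm(n * J), n, J)
    if (a > 0 && J > 1L) {
      s <- sqrt(1 - a^2)
      for (j in 2:J) Z[, j] <- a * Z[, j - 1L] + s * Z[, j]
    }
    Z < matrix(thr, n, J, byrow = TRUE)
  }
  G <- with_seed(seed, {
    h1 <- one_haplotype()
    h2 <- one_haplotype()
    h1 + h2
  })
  storage.mode(G) <- "integer"
  colnames(G) <- config$variant_ids
  attr(G, "maf") <- config$maf
  G
}

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation r,
# by one-dimensional quadrature.
bvn_lower <- function(a, b, r) {
  if (abs(r) < 1e-12) return(pnorm(a) * pnorm(b))
  if (r > 1 - 1e-12) return(pnorm(min(a, b)))
  s <- sqrt(1 - r^2)
  integrate(function(z) dnorm(z) * pnorm((b - r * z) / s),
            -Inf, a, rel.tol = 1e-10)$value
}

#' Closed-form signed LD matrix of the genotype model
#'
#' Correlation between dosages at variants i and j under the
#' haplotype-threshold model: with latent correlation `r = ld_decay^|i-j|`
#' and thresholds at the MAF quantiles, the allele indicators have
#' correlation `(P2(qi, qj, r) - pi pj) / sqrt(pi(1-pi) pj(1-pj))` where
#' `P2` is the bivariate normal lower orthant probability; summing two
#' independent haplotypes leaves the correlation unchanged.
#'
#' @param config a [sim_config].
#' @return J x J signed correlation matrix with variant-id dimnames.
#' @export
true_ld_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_variants
  p <- config$maf
  R <- diag(J)
  a <- config$ld_decay
  if (a > 0 && J > 1L) {
    q <- qnorm(p)
    for (i in 1:(J - 1L)) for (j in (i + 1L):J) {
      r <- a^(j - i)
      if (r < 1e-8) next
      pr <- bvn_lower(q[i], q[j], r)
      R[i, j] <- R[j, i] <-
        (pr - p[i] * p[j]) / sqrt(p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
    }
  }
  dimnames(R) <- list(config$variant_ids, config$variant_ids)
  R
}
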
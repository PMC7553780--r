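#' Simulate lipid phenotypes from genotypes
#'
#' Each subfraction (LDL, HDL, TG) is `genotypes %*% effects` plus
#' correlated Gaussian noise scaled so the raw trait has unit variance,
#' then standardized to mean 0, variance 1 (mirroring rank-normalized
#' consortium phenotypes). Total cholesterol is a deterministic positive
#' combination of the standardized subfractions, rescaled to unit
#' variance, so polygenic univariable (TC) and multivariable (LDL/HDL/TG)
#' analyses are both meaningful.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()].
#' @param config a [sim_config].
#' @param seed RNG seed for the environmental noise.
#' @return n x 4 matrix with columns LDL, HDL, TG, TC.
#' @export
simulate_lipids <- function(genotypes, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (ncol(genotypes) != nrow(config$exposure_effects))
    stop("genotype columns do not match exposure_effects rows")
  n <- nrow(genotypes)
  g <- genotypes %*% config$exposure_effects
  vg <- diag(genetic_variance(config))
  s_eps <- sqrt(pmax(1 - vg, 0.05))
  noise <- with_seed(seed, matrix(rnorm(n * 3L), n, 3L)) %*%
    chol(config$lipid_cor)
  noise <- sweep(noise, 2L, s_eps, `*`)
  lip <- scale(g + noise)
  tc <- scale(lip %*% config$tc_weights)
  out <- cbind(lip, tc)
  colnames(out) <- c("LDL", "HDL", "TG", "TC")
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Simulate covariates
#'
#' Age uniform on 40-70 years, sex Bernoulli (54.1% female, coded 1), and
#' ten standard-normal genomic principal components. These exercise the
#' covariate-adjustment path without demographic realism claims.
#'
#' @param config a [sim_config].
#' @param n number of individuals.
#' @param seed RNG seed.
#' @return data.frame with columns `age`, `sex` (1 = female) and
#'   `PC1`..`PC10`.
#' @export
simulate_covariates <- function(config, n, seed = config$seed + 2L) {
  with_seed(seed, {
    cov <- data.frame(age = runif(n, 40, 70),
                      sex = rbinom(n, 1L, 0.541))
    pcs <- matrix(rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    cbind(cov, pcs)
  })
}

# Direct per-allele genotype->outcome effects for a pleiotropy mode.
# Directional pleiotropy is defined relative to the LDL-raising allele
# (the orientation convention of MR-Egger): each variant's direct effect
# has mean pleiotropy_mean on its LDL-increasing allele, so the average
# pleiotropy does not cancel across sign-symmetric exposure effects.
pleiotropy_effects <- function(config, mode = config$pleiotropy_mode,
                               seed = config$seed) {
  J <- config$n_variants
  switch(mode,
    none = numeric(J),
    balanced = with_seed(child_seed(seed, 3L),
                         rnorm(J, 0, config$pleiotropy_sd)),
    directional = {
      s <- sign(config$exposure_effects[, "LDL"])
      s[s == 0] <- 1
      with_seed(child_seed(seed, 3L),
                rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd)) * s
    },
    non_lipid_pathway = {
      delta <- numeric(J)
      delta[config$region_variants] <- config$direct_effect
      delta
    })
}

#' Simulate a binary outcome
#'
#' `P(case) = plogis(alpha + lipids %*% theta + genotype pleiotropy +
#' covariate effects)`; the intercept `alpha` is solved by bisection so the
#' marginal case fraction matches the configured K to within 1e-4. Under
#' `pleiotropy_mode = "non_lipid_pathway"` the designated region variants
#' receive a direct per-allele effect independent of lipid levels (a
#' drug-target region acting through a non-lipid pathway).
#'
#' @param genotypes,lipids,covariates simulated inputs.
#' @param config a [sim_config].
#' @param seed RNG seed.
#' @param override named list overriding `case_fraction`, `causal_effects`,
#'   `pleiotropy_mode`, `pleiotropy_sd`, `pleiotropy_mean`,
#'   `region_variants`, `direct_effect`, or adding `sex_restriction`.
#' @return Integer 0/1 vector with the solved intercept in
#'   `attr(, "intercept")`.
#' @export
simulate_outcome <- function(genotypes, lipids, covariates, config,
                             seed = config$seed + 3L, override = list()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  for (f in intersect(names(override),
                      c("case_fraction", "causal_effects", "pleiotropy_mode",
                        "pleiotropy_sd", "pleiotropy_mean", "region_variants",
                        "direct_effect")))
    cfg[[f]] <- override[[f]]
  K <- cfg$case_fraction
  stopifnot(K > 0, K < 1)
  theta <- cfg$causal_effects
  eta <- drop(lipids[, c("LDL", "HDL", "TG")] %*% theta)
  delta <- pleiotropy_effects(cfg, seed = seed)
  if (any(delta != 0)) eta <- eta + drop(genotypes %*% delta)
  ce <- cfg$covariate_effects
  eta <- eta + ce$age * (covariates$age - mean(covariates$age)) +
    ce$sex * covariates$sex
  if (any(ce$pc != 0)) {
    pcs <- as.matrix(covariates[, paste0("PC", 1:10)])
    eta <- eta + drop(pcs %*% rep_len(ce$pc, 10L))
  }
  f <- function(a) mean(plogis(a + eta)) - K
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf(
      "case fraction %.4g unattainable: achievable range [%.4g, %.4g]",
      K, mean(plogis(lo + eta)), mean(plogis(hi + eta))))
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f((lo + hi) / 2)) < 1e-6) break
  }
  alpha <- (lo + hi) / 2
  pr <- plogis(alpha + eta)
  y <- with_seed(seed, rbinom(length(pr), 1L, pr))
  restrict <- override$sex_restriction %||% "none"
  if (restrict == "female") y[covariates$sex == 0L] <- 0L
  if (restrict == "male") y[covariates$sex == 1L] <- 0L
  attr(y, "intercept") <- alpha
  y
}
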
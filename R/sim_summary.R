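#' Simulate two-sample MR summary statistics directly
#'
#' Draws per-variant association estimates from their asymptotic sampling
#' distributions at the configured sample sizes, bypassing individual-level
#' simulation. The generative model is the same as the cohort path:
#' per-allele conditional lipid effects from `config$exposure_effects`
#' (marginalized through the signed LD matrix), total cholesterol as the
#' deterministic subfraction combination, outcome log-odds
#' `gamma = B_marginal %*% theta + pleiotropy`, exposure SEs
#' `1/(sigma_j sqrt(n1))` and outcome SEs
#' `1/(sigma_j sqrt(n2 K (1-K)))` with `sigma_j = sqrt(2 p_j (1-p_j))`,
#' and estimation errors correlated across variants according to the LD
#' matrix within each sample (independent between the two samples).
#'
#' This is the workhorse for replicate-heavy calibration studies (type-I
#' error, CI coverage, pleiotropy-intercept behaviour) where hundreds of
#' full cohorts would be wasteful; its agreement with the individual-level
#' path is checked in the test suite.
#'
#' @param config a [sim_config].
#' @param seed RNG seed for this draw (pleiotropy effects are re-drawn per
#'   seed in the balanced/directional modes).
#' @param traits exposure traits to report.
#' @param outcome_name label for the outcome trait.
#' @return list with `exposure` and `outcome` summary-statistics
#'   data.frames, the signed LD matrix `ld`, and `truth` (true marginal
#'   effects, outcome effects `gamma`, pleiotropy `delta`, `theta`).
#' @export
sim_summary_stats <- function(config, seed = config$seed,
                              traits = c("LDL", "HDL", "TG", "TC"),
                              outcome_name = "overall") {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_variants
  p <- config$maf
  sig <- sqrt(2 * p * (1 - p))
  R <- true_ld_matrix(config)
  # conditional per-allele effects on the four traits
  tc <- tc_effects(config, R)
  Bcond <- cbind(config$exposure_effects, TC = tc$beta)
  # marginal per-allele effects: D^-1 R D b
  marg <- function(b) drop(R %*% (b * sig)) / sig
  Bmarg <- apply(Bcond, 2L, marg)
  theta <- config$causal_effects
  delta <- pleiotropy_effects(config, seed = child_seed(seed, 31L))
  gamma <- drop(Bmarg[, c("LDL", "HDL", "TG")] %*% theta) + marg(delta)

  n1 <- config$n_exposure_sample
  n2 <- config$n_outcome_sample
  K <- config$case_fraction
  se_x <- 1 / (sig * sqrt(n1))
  se_y <- 1 / (sig * sqrt(n2 * K * (1 - K)))
  Lt <- t(chol(R + diag(1e-10, J)))
  corr_noise <- function() drop(Lt %*% rnorm(J))

  draws <- with_seed(child_seed(seed, 32L), {
    bx_hat <- sapply(traits, function(tr) Bmarg[, tr] + se_x * corr_noise())
    by_hat <- gamma + se_y * corr_noise()
    list(bx = bx_hat, by = by_hat)
  })

  base <- data.frame(variant_id = config$variant_ids, chr = 1L,
                     pos = seq_len(J) * 1000L,
                     effect_allele = "A", other_allele = "G", eaf = p,
                     stringsAsFactors = FALSE)
  exposure <- do.call(rbind, lapply(traits, function(tr) {
    b <- draws$bx[, tr]
    cbind(base, data.frame(beta = b, se = se_x,
                           pvalue = 2 * pnorm(-abs(b / se_x)),
                           n = n1, trait = tr, stringsAsFactors = FALSE))
  }))
  rownames(exposure) <- NULL
  outcome <- cbind(base, data.frame(
    beta = draws$by, se = se_y,
    pvalue = 2 * pnorm(-abs(draws$by / se_y)),
    n = n2, trait = outcome_name, stringsAsFactors = FALSE))
  list(exposure = exposure, outcome = outcome, ld = R,
       truth = list(beta_marginal = Bmarg, gamma = gamma, delta = delta,
                    theta = theta))
}
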
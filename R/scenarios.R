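# Named simulation scenarios used by the calibration studies and the
# acceptance script. These encode the study conditions once: consortium
# exposure sample of 188,577, outcome scan of 367,703 with 20.4% cases,
# 184 polygenic lipid variants (14.6%/13.7%/11.7% of LDL/HDL/TG variance),
# and a statin-target-like gene region explaining 0.4% of LDL variance.

scale_effects_to <- function(b, idx, target, sig) {
  b[idx] * sqrt(target / sum((b[idx] * sig[idx])^2))
}

#' Headline drug-target scenario: a gene region acting through a
#' non-lipid pathway
#'
#' Builds the package's central simulation scenario: 184 polygenic lipid
#' variants with no causal lipid effect on the outcome, plus a separate
#' 5-variant drug-target region (a distinct conditional-analysis list, as
#' gene-region proxy variants are in practice) explaining 0.4% of LDL
#' variance and carrying a direct per-allele effect on the outcome of
#' `log(region_or)` per SD of LDL -- independent of lipid levels. Under
#' this mechanism the gene-region MR estimate is nonzero while the
#' polygenic LDL estimate stays null.
#'
#' @param seed base seed for the configuration.
#' @param region_or odds ratio per SD LDL carried by the region's direct
#'   (non-lipid) pathway; default 1.32.
#' @param theta causal subfraction effects (default all zero).
#' @return list with `config` (a [sim_config] of 189 variants),
#'   `region` (a [region_spec] over the last 5), and `poly_ids`
#'   (the 184 polygenic variant ids).
#' @export
headline_scenario <- function(seed = 104L, region_or = 1.32,
                              theta = c(LDL = 0, HDL = 0, TG = 0)) {
  J <- 189L
  base <- sim_config(seed = seed, n_variants = J)
  sig <- sqrt(2 * base$maf * (1 - base$maf))
  eff <- with_seed(child_seed(seed, 7L), matrix(rnorm(J * 3L), J, 3L))
  colnames(eff) <- c("LDL", "HDL", "TG")
  poly <- 1:184; region <- 185:189
  eff[poly, "LDL"] <- scale_effects_to(eff[, "LDL"], poly, 0.146, sig)
  eff[region, "LDL"] <- scale_effects_to(eff[, "LDL"], region, 0.004, sig)
  eff[poly, "HDL"] <- scale_effects_to(eff[, "HDL"], poly, 0.137, sig)
  eff[region, "HDL"] <- scale_effects_to(eff[, "HDL"], region, 0.0005, sig)
  eff[poly, "TG"] <- scale_effects_to(eff[, "TG"], poly, 0.117, sig)
  eff[region, "TG"] <- scale_effects_to(eff[, "TG"], region, 0.0005, sig)
  cfg <- sim_config(seed = seed, n_variants = J, exposure_effects = eff,
                    n_exposure_sample = 188577L, n_outcome_sample = 367703L,
                    case_fraction = 0.204, causal_effects = theta,
                    pleiotropy_mode = "non_lipid_pathway",
                    region_variants = region,
                    direct_effect = log(region_or) * eff[region, "LDL"])
  list(config = cfg,
       region = region_spec("HMGCR", cfg$variant_ids[region],
                            variance_explained = 0.004),
       poly_ids = cfg$variant_ids[poly])
}

#' Pleiotropy-calibration scenario for MR-Egger
#'
#' A 60-variant instrument set whose LDL effects are all nonzero (as
#' significance-selected instruments are -- a zero-effect instrument would
#' be randomly sign-oriented, washing out the recovered intercept), at the
#' study sample sizes, with balanced or directional per-variant direct
#' effects on the outcome.
#'
#' @param mode `"balanced"` or `"directional"`.
#' @param seed base seed.
#' @param pleiotropy_sd SD of the per-variant direct effects (log-odds per
#'   allele).
#' @param pleiotropy_mean mean direct effect on the LDL-raising allele
#'   (directional mode).
#' @return A [sim_config].
#' @export
egger_scenario <- function(mode = c("balanced", "directional"),
                           seed = 103L, pleiotropy_sd = 0.004,
                           pleiotropy_mean = 0.008) {
  mode <- match.arg(mode)
  J <- 60L
  eff <- with_seed(child_seed(seed, 8L), {
    cbind(LDL = runif(J, 0.03, 0.3) * sample(c(-1, 1), J, replace = TRUE),
          HDL = rnorm(J, 0, 0.02), TG = rnorm(J, 0, 0.02))
  })
  sim_config(seed = seed, n_variants = J, exposure_effects = eff,
             n_exposure_sample = 188577L, n_outcome_sample = 367703L,
             case_fraction = 0.204, pleiotropy_mode = mode,
             pleiotropy_sd = pleiotropy_sd,
             pleiotropy_mean = if (mode == "directional") pleiotropy_mean else 0)
}
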
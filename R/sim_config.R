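#' Simulation configuration for the synthetic two-sample MR study
#'
#' Defines the full generative model: genotypes with autoregressive LD,
#' three lipid subfractions (LDL, HDL, triglycerides) in SD units plus
#' total cholesterol as a deterministic positive combination, covariates,
#' and a logistic binary outcome with configurable pleiotropy. Defaults
#' emulate the study conditions: 184 lipid-associated variants explaining
#' 14.6%/13.7%/11.7% of LDL/HDL/TG variance, an exposure sample of 188,577,
#' an outcome scan of 367,703 individuals, and an overall-cancer case
#' fraction of 20.4%.
#'
#' Identical `(seed, config)` give bit-identical simulation output: all
#' derived quantities (allele frequencies, default effect sizes) are drawn
#' from seeds deterministically derived from `seed`.
#'
#' @param seed integer base seed.
#' @param n_exposure_sample,n_outcome_sample cohort sizes for the two
#'   non-overlapping samples.
#' @param n_variants number of variants.
#' @param maf_range range of minor-allele frequencies, strictly inside
#'   (0, 1).
#' @param ld_decay latent autoregressive correlation in `[0, 1)`; the
#'   haplotype-threshold model makes the implied signed dosage LD matrix
#'   available in closed form via [true_ld_matrix()].
#' @param exposure_effects optional J x 3 matrix of per-allele effects (SD
#'   units) on LDL, HDL, TG. When `NULL` a sparse random matrix is
#'   generated and scaled so each column's variance explained matches
#'   `target_r2`.
#' @param causal_effects named vector `c(LDL=, HDL=, TG=)` of per-SD
#'   log-odds effects on the outcome.
#' @param pleiotropy_mode one of `"none"`, `"balanced"`, `"directional"`,
#'   `"non_lipid_pathway"`.
#' @param pleiotropy_sd SD of per-variant direct (non-lipid) effects for
#'   the balanced/directional modes.
#' @param pleiotropy_mean mean of directional pleiotropy, applied to each
#'   variant's LDL-raising allele (the MR-Egger orientation convention);
#'   defaults to `pleiotropy_sd` when mode is `"directional"`, else 0.
#' @param region_variants variant indices of the drug-target gene region
#'   receiving a direct effect under `"non_lipid_pathway"`.
#' @param direct_effect per-allele log-odds direct effect for the region
#'   variants under `"non_lipid_pathway"` (scalar or one per region
#'   variant).
#' @param case_fraction marginal case fraction K in (0, 1).
#' @param covariate_effects list of log-odds effects: `age` (per year),
#'   `sex` (female vs male), `pc` (per principal component SD).
#' @param lipid_cor 3 x 3 residual correlation matrix between the lipid
#'   fractions (LDL, HDL, TG). The source consortium's phenotype
#'   covariance is not published; defaults are typical epidemiological
#'   values and are configurable, not calibrated.
#' @param tc_weights positive weights combining the standardized LDL, HDL
#'   and TG components into total cholesterol (rescaled to unit variance).
#' @param target_r2 per-fraction variance explained by the variant set,
#'   used only when `exposure_effects` is generated.
#' @param selfreport_fraction fraction of cases flagged as self-report
#'   only.
#' @param outcomes optional named list defining multiple outcomes; each
#'   element is a list overriding `case_fraction`, `causal_effects`,
#'   `pleiotropy_mode`, `pleiotropy_sd`, `pleiotropy_mean`,
#'   `region_variants`, `direct_effect` and/or adding `sex_restriction`
#'   (`"none"`, `"female"`, `"male"`). Default: one outcome `"overall"`
#'   from the top-level fields.
#' @return An object of class `sim_config` with derived fields `maf`
#'   (allele frequencies) and `exposure_effects` filled in.
#' @export
sim_config <- function(seed = 1L,
                       n_exposure_sample = 188577L,
                       n_outcome_sample = 367703L,
                       n_variants = 184L,
                       maf_range = c(0.05, 0.5),
                       ld_decay = 0,
                       exposure_effects = NULL,
                       causal_effects = c(LDL = 0, HDL = 0, TG = 0),
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "non_lipid_pathway"),
                       pleiotropy_sd = 0,
                       pleiotropy_mean = NULL,
                       region_variants = integer(0),
                       direct_effect = 0,
                       case_fraction = 0.204,
                       covariate_effects = list(age = 0.02, sex = -0.1, pc = 0),
                       lipid_cor = default_lipid_cor(),
                       tc_weights = c(LDL = 1, HDL = 0.4, TG = 0.45),
                       target_r2 = c(LDL = 0.146, HDL = 0.137, TG = 0.117),
                       selfreport_fraction = 0.057,
                       outcomes = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_exposure_sample >= 1, n_outcome_sample >= 1, n_variants >= 1,
            length(maf_range) == 2L,
            all(maf_range > 0), all(maf_range < 1),
            maf_range[1L] <= maf_range[2L],
            pleiotropy_sd >= 0,
            case_fraction > 0, case_fraction < 1,
            all(tc_weights > 0))
  if (ld_decay < 0 || ld_decay >= 1)
    stop("ld_decay must lie in [0, 1)")
  if (!all(c("LDL", "HDL", "TG") %in% names(causal_effects)))
    stop("causal_effects must be named with LDL, HDL, TG")
  causal_effects <- causal_effects[c("LDL", "HDL", "TG")]
  lipid_cor <- as.matrix(lipid_cor)
  stopifnot(all(dim(lipid_cor) == c(3L, 3L)),
            max(abs(lipid_cor - t(lipid_cor))) < 1e-8,
            all(abs(diag(lipid_cor) - 1) < 1e-8))
  if (is.null(pleiotropy_mean))
    pleiotropy_mean <- if (pleiotropy_mode == "directional") pleiotropy_sd else 0
  if (pleiotropy_mode == "non_lipid_pathway" && length(region_variants) == 0L)
    stop("non_lipid_pathway mode needs region_variants")
  if (length(region_variants) > 0L &&
      (any(region_variants < 1) || any(region_variants > n_variants)))
    stop("region_variants out of range")

  maf <- with_seed(child_seed(seed, 1L),
                   runif(n_variants, maf_range[1L], maf_range[2L]))
  cfg <- structure(list(
    seed = as.integer(seed),
    n_exposure_sample = as.integer(n_exposure_sample),
    n_outcome_sample = as.integer(n_outcome_sample),
    n_variants = as.integer(n_variants),
    maf_range = maf_range, maf = maf, ld_decay = ld_decay,
    exposure_effects = NULL,
    causal_effects = causal_effects,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
    pleiotropy_mean = pleiotropy_mean,
    region_variants = as.integer(region_variants),
    direct_effect = direct_effect,
    case_fraction = case_fraction,
    covariate_effects = covariate_effects,
    lipid_cor = lipid_cor, tc_weights = tc_weights,
    target_r2 = target_r2,
    selfreport_fraction = selfreport_fraction,
    outcomes = outcomes,
    variant_ids = sprintf("var_%03d", seq_len(n_variants))),
    class = "sim_config")

  if (is.null(exposure_effects)) {
    cfg$exposure_effects <- default_exposure_effects(cfg)
  } else {
    exposure_effects <- as.matrix(exposure_effects)
    if (nrow(exposure_effects) != n_variants || ncol(exposure_effects) != 3L)
      stop("exposure_effects must be n_variants x 3 (LDL, HDL, TG)")
    colnames(exposure_effects) <- c("LDL", "HDL", "TG")
    cfg$exposure_effects <- exposure_effects
  }
  vg <- genetic_variance(cfg)
  if (any(diag(vg) >= 0.95))
    stop("exposure effects explain >= 95% of a lipid fraction's variance")
  cfg
}

default_lipid_cor <- function() {
  m <- matrix(c(1, -0.1, 0.2,
                -0.1, 1, -0.4,
                0.2, -0.4, 1), 3L, 3L)
  dimnames(m) <- list(c("LDL", "HDL", "TG"), c("LDL", "HDL", "TG"))
  m
}

# Sparse random per-allele effects, scaled per column so the variance
# explained (including LD cross terms) hits target_r2.
default_exposure_effects <- function(cfg) {
  J <- cfg$n_variants
  with_seed(child_seed(cfg$seed, 2L), {
    incl <- matrix(rbinom(J * 3L, 1L, 0.55), J, 3L)
    none <- rowSums(incl) == 0L
    incl[cbind(which(none), sample.int(3L, sum(none), replace = TRUE))] <- 1L
    eff <- matrix(rnorm(J * 3L), J, 3L) * incl
  })
  colnames(eff) <- c("LDL", "HDL", "TG")
  R <- true_ld_matrix(cfg)
  sig <- sqrt(2 * cfg$maf * (1 - cfg$maf))
  for (k in 1:3) {
    b <- eff[, k] * sig
    v <- drop(t(b) %*% R %*% b)
    eff[, k] <- eff[, k] * sqrt(cfg$target_r2[k] / v)
  }
  eff
}

# 3x3 genetic covariance of the standardized lipid fractions implied by
# the per-allele effects and the signed LD matrix.
genetic_variance <- function(cfg, R = NULL) {
  R <- R %||% true_ld_matrix(cfg)
  sig <- sqrt(2 * cfg$maf * (1 - cfg$maf))
  B <- cfg$exposure_effects * sig
  t(B) %*% R %*% B
}

# Phenotypic 3x3 covariance (genetic + residual) of LDL, HDL, TG; unit
# diagonal by construction.
phenotypic_cov <- function(cfg, R = NULL) {
  G <- genetic_variance(cfg, R)
  s_eps <- sqrt(pmax(1 - diag(G), 0))
  G + cfg$lipid_cor * outer(s_eps, s_eps)
}

# Per-allele effects on standardized total cholesterol implied by the
# deterministic combination of the standardized subfractions.
tc_effects <- function(cfg, R = NULL) {
  w <- cfg$tc_weights
  C <- phenotypic_cov(cfg, R)
  v <- drop(t(w) %*% C %*% w)
  list(beta = drop(cfg$exposure_effects %*% w) / sqrt(v), var = v)
}

#' Subfraction causal effects equivalent to a total-cholesterol effect
#'
#' Because total cholesterol is a deterministic combination of the
#' standardized subfractions, a causal effect of `theta_tc` per SD of TC
#' on the outcome is generatively identical to the subfraction effect
#' vector `theta_tc * w / sd(w'lipids)`. Useful for simulating a
#' TC-mediated outcome with the subfraction-parameterized generator.
#'
#' @param config a [sim_config].
#' @param theta_tc log-OR per SD of total cholesterol.
#' @return Named vector `c(LDL=, HDL=, TG=)` to use as `causal_effects`.
#' @export
causal_via_tc <- function(config, theta_tc) {
  w <- config$tc_weights
  v <- drop(t(w) %*% phenotypic_cov(config) %*% w)
  setNames(theta_tc * w / sqrt(v), c("LDL", "HDL", "TG"))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic two-sample MR configuration (seed %d)\n",
    "  %d variants, MAF %.2f-%.2f, ld_decay %.2f\n",
    "  exposure sample n = %d, outcome sample n = %d, case fraction %.3f\n",
    "  causal log-OR per SD: LDL %.3f, HDL %.3f, TG %.3f\n",
    "  pleiotropy: %s (sd %.3g)\n"),
    x$seed, x$n_variants, x$maf_range[1L], x$maf_range[2L], x$ld_decay,
    x$n_exposure_sample, x$n_outcome_sample, x$case_fraction,
    x$causal_effects[1L], x$causal_effects[2L], x$causal_effects[3L],
    x$pleiotropy_mode, x$pleiotropy_sd))
  invisible(x)
}
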
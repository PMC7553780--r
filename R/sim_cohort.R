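#' Simulate a full cohort
#'
#' Genotypes, lipid phenotypes, covariates and one or more binary outcomes
#' (per `config$outcomes`; a single `"overall"` outcome from the top-level
#' config fields when unset), plus a self-report-only flag on a random
#' subset of cases and an any-cancer indicator.
#'
#' @param config a [sim_config].
#' @param n cohort size.
#' @param seed RNG seed; distinct sub-seeds drive genotypes, phenotypes,
#'   covariates and each outcome.
#' @return An object of class `cohort_data`: list with elements
#'   `genotypes`, `lipids`, `covariates`, `outcomes` (n x m 0/1 matrix),
#'   `selfreport_only`, `any_cancer`, `variant_info` and `config`.
#' @export
simulate_cohort <- function(config, n = config$n_outcome_sample,
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  G <- simulate_genotypes(config, n, seed = child_seed(seed, 11L))
  lip <- simulate_lipids(G, config, seed = child_seed(seed, 12L))
  cov <- simulate_covariates(config, n, seed = child_seed(seed, 13L))
  defs <- config$outcomes %||% list(overall = list())
  outcomes <- sapply(seq_along(defs), function(i)
    simulate_outcome(G, lip, cov, config,
                     seed = child_seed(seed, 20L + i),
                     override = defs[[i]]))
  outcomes <- matrix(outcomes, nrow = n,
                     dimnames = list(NULL, names(defs)))
  any_cancer <- rowSums(outcomes) > 0L
  selfreport <- with_seed(child_seed(seed, 19L),
                          rbinom(n, 1L, config$selfreport_fraction) == 1L)
  structure(list(
    genotypes = G, lipids = lip, covariates = cov,
    outcomes = outcomes,
    selfreport_only = any_cancer & selfreport,
    any_cancer = any_cancer,
    variant_info = data.frame(variant_id = config$variant_ids,
                              chr = 1L, pos = seq_len(config$n_variants) * 1000L,
                              effect_allele = "A", other_allele = "G",
                              stringsAsFactors = FALSE),
    config = config), class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d variants, outcomes: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(colnames(x$outcomes), collapse = ", ")))
  invisible(x)
}

#' Simulate the two non-overlapping samples of a two-sample MR design
#'
#' Two disjoint cohorts drawn from the same variant frequencies, LD
#' structure and generative model with independent noise: exposure summary
#' statistics are computed only from the first, outcome associations only
#' from the second, so estimation errors are uncorrelated between samples.
#'
#' @param config a [sim_config].
#' @param seed base seed; re-running with the same seed and config gives
#'   an identical pair.
#' @return list with elements `exposure` and `outcome`, both
#'   `cohort_data`.
#' @export
make_two_samples <- function(config, seed = config$seed) {
  list(exposure = simulate_cohort(config, config$n_exposure_sample,
                                  seed = child_seed(seed, 101L)),
       outcome = simulate_cohort(config, config$n_outcome_sample,
                                 seed = child_seed(seed, 202L)))
}

#' Per-variant exposure associations from an individual-level cohort
#'
#' Linear regression of each standardized lipid fraction on each variant's
#' dosage (the exposure-side stand-in for consortium summary statistics).
#'
#' @param cohort a `cohort_data` object.
#' @param traits lipid columns to scan (default all four).
#' @return A summary-statistics data.frame (one row per variant x trait).
#' @export
exposure_scan <- function(cohort, traits = colnames(cohort$lipids)) {
  G <- cohort$genotypes
  n <- nrow(G)
  vi <- cohort$variant_info
  eaf <- colMeans(G) / 2
  res <- lapply(traits, function(tr) {
    y <- cohort$lipids[, tr]
    # per-variant simple regression, vectorized
    gc <- sweep(G, 2L, colMeans(G))
    ssx <- colSums(gc^2)
    beta <- drop(crossprod(gc, y - mean(y))) / ssx
    resid_var <- vapply(seq_len(ncol(G)), function(j)
      sum((y - mean(y) - gc[, j] * beta[j])^2) / (n - 2L), numeric(1L))
    se <- sqrt(resid_var / ssx)
    data.frame(variant_id = vi$variant_id, chr = vi$chr, pos = vi$pos,
               effect_allele = vi$effect_allele,
               other_allele = vi$other_allele,
               eaf = eaf, beta = beta, se = se,
               pvalue = 2 * pnorm(-abs(beta / se)),
               n = n, trait = tr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a simulated cohort to tab-separated files
#'
#' One genotype matrix file, one phenotype/covariate file and the exact
#' signed LD matrix (from [true_ld_matrix()]).
#'
#' @param cohort a `cohort_data` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, "genotypes.tsv")
  ppath <- file.path(dir, "phenotypes.tsv")
  lpath <- file.path(dir, "ld_matrix.tsv")
  geno <- as.data.frame(cohort$genotypes)
  write.table(geno, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  phen <- data.frame(cohort$lipids, cohort$covariates,
                     cohort$outcomes,
                     selfreport_only = as.integer(cohort$selfreport_only),
                     any_cancer = as.integer(cohort$any_cancer))
  write.table(phen, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  write_ld_matrix(true_ld_matrix(cohort$config), lpath)
  invisible(c(genotypes = gpath, phenotypes = ppath, ld = lpath))
}
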
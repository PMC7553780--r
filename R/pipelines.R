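#' Gene-region drug-target proxy analysis
#'
#' Harmonizes the region variants' associations with the region's scaling
#' trait against the outcome, validates the pairwise r-squared rule, and
#' fits the correlated-variant IVW estimator (random effects by default).
#' The estimate is expressed per one SD increase in the scaling trait
#' (LDL-cholesterol or triglycerides).
#'
#' @param region a [region_spec].
#' @param exposure_stats exposure summary statistics containing the
#'   region's scaling trait (conditional betas when available).
#' @param outcome_stats outcome summary statistics (log-odds).
#' @param ld signed LD matrix covering the region variants.
#' @param random_effects passed to [ivw_correlated()].
#' @return An [mr_estimate] annotated with `gene`.
#' @export
run_gene_region <- function(region, exposure_stats, outcome_stats, ld,
                            random_effects = TRUE) {
  stopifnot(inherits(region, "region_spec"))
  tr <- region$scaling_trait
  exp_sub <- exposure_stats[exposure_stats$trait == tr &
                              exposure_stats$variant_id %in% region$variants, ]
  miss_e <- setdiff(region$variants, exp_sub$variant_id)
  miss_o <- setdiff(region$variants, outcome_stats$variant_id)
  if (length(miss_e) > 0L || length(miss_o) > 0L)
    stop("region variants missing from summary data: ",
         paste(unique(c(miss_e, miss_o)), collapse = ", "))
  # re-validate the r2 rule against the supplied LD
  region_spec(region$gene, region$variants, region$scaling_trait,
              region$variance_explained, ld = ld,
              r2_threshold = region$r2_threshold)
  h <- harmonize(exp_sub, outcome_stats[outcome_stats$variant_id %in%
                                          region$variants, ],
                 ld = ld, exposures = tr)
  est <- ivw_correlated(h, random_effects = random_effects)
  est$flags$gene <- region$gene
  est
}

#' Polygenic lipid analysis
#'
#' The polygenic arm of the study: multivariable IVW jointly for
#' LDL-cholesterol, HDL-cholesterol and triglycerides (each fraction's
#' direct effect conditional on the others), and univariable IVW for total
#' cholesterol, all with random-effects scaling and heterogeneity
#' statistics attached to every row.
#'
#' @param exposure_stats exposure summary statistics holding the traits in
#'   `mv_exposures` and `tc_trait`.
#' @param outcome_stats outcome summary statistics for one endpoint.
#' @param ld optional signed LD matrix (identity when `NULL`).
#' @param mv_exposures traits entering the multivariable model.
#' @param tc_trait total-cholesterol trait label (skipped when absent or
#'   `NULL`).
#' @param random_effects logical.
#' @return Estimates data.frame, one row per exposure.
#' @export
run_polygenic <- function(exposure_stats, outcome_stats, ld = NULL,
                          mv_exposures = c("LDL", "HDL", "TG"),
                          tc_trait = "TC", random_effects = TRUE) {
  present <- intersect(mv_exposures, unique(exposure_stats$trait))
  ests <- list()
  if (length(present) >= 2L) {
    h <- harmonize(exposure_stats, outcome_stats, ld = ld,
                   exposures = present)
    ests <- mvmr_ivw(h, random_effects = random_effects)
  } else if (length(present) == 1L) {
    # degraded single-exposure input: univariable analysis
    h <- harmonize(exposure_stats, outcome_stats, ld = ld,
                   exposures = present)
    ests <- list(ivw_correlated(h, random_effects = random_effects))
  }
  if (!is.null(tc_trait) && tc_trait %in% unique(exposure_stats$trait)) {
    h_tc <- harmonize(exposure_stats, outcome_stats, ld = ld,
                      exposures = tc_trait)
    ests <- c(ests, list(ivw_correlated(h_tc,
                                        random_effects = random_effects)))
  }
  if (length(ests) == 0L) stop("no usable exposure traits found")
  estimates_table(ests)
}

#' Robust-method follow-up of significant polygenic results
#'
#' For every estimate row with `p < threshold`, appends the univariable
#' MR-Egger estimate, the multivariable MR-Egger estimate (when several
#' exposures are available) and the weighted median estimate computed
#' after LD pruning. Each appended row carries an `attenuated` flag set
#' when the robust point estimate disagrees in sign with the primary
#' estimate or shrinks by more than half toward zero.
#'
#' @param est_table estimates data.frame from [run_polygenic()].
#' @param exposure_stats,outcome_stats,ld the inputs the table was
#'   computed from.
#' @param threshold significance threshold for follow-up (default 0.01).
#' @param r2_prune squared-correlation threshold for the weighted-median
#'   pruning step.
#' @param mv_exposures traits of the multivariable model.
#' @param n_boot,seed weighted-median bootstrap controls.
#' @return The extended table with columns `followup_of` and `attenuated`
#'   (both `NA` for primary rows); unchanged when nothing is significant.
#' @export
robust_followup <- function(est_table, exposure_stats, outcome_stats,
                            ld = NULL, threshold = 0.01, r2_prune = 0.4,
                            mv_exposures = c("LDL", "HDL", "TG"),
                            n_boot = 1000L, seed = 1L) {
  est_table$followup_of <- NA_character_
  est_table$attenuated <- NA
  sig <- which(est_table$p < threshold)
  if (length(sig) == 0L) return(est_table)
  extra <- list()
  for (i in sig) {
    tr <- est_table$exposure[i]
    primary <- est_table$beta[i]
    h_uni <- harmonize(exposure_stats, outcome_stats, ld = ld,
                       exposures = tr)
    robust <- list(mr_egger(h_uni))
    present <- intersect(mv_exposures, unique(exposure_stats$trait))
    if (tr %in% present && length(present) >= 2L) {
      h_mv <- harmonize(exposure_stats, outcome_stats, ld = ld,
                        exposures = present)
      robust <- c(robust, list(mvmr_egger(h_mv,
                                          orient_by = match(tr, present))[[tr]]))
    }
    h_pruned <- prune_correlated(h_uni, r2_threshold = r2_prune)
    robust <- c(robust, list(weighted_median(h_pruned, n_boot = n_boot,
                                             seed = seed)))
    for (r in robust) {
      row <- as.data.frame(r)
      row$followup_of <- tr
      row$attenuated <- sign(r$beta) != sign(primary) ||
        abs(r$beta) < 0.5 * abs(primary)
      extra <- c(extra, list(row))
    }
  }
  rbind(est_table, do.call(rbind, extra))
}

#' Combined endpoint analysis
#'
#' Re-scans the outcome cohort for a combined endpoint whose case set is
#' the union of the member case sets (a person with two member cancers
#' counts once), then runs the polygenic pipeline on the combined summary
#' statistics.
#'
#' @param cohort the outcome-sample `cohort_data`.
#' @param members character vector (>= 2) of member outcome names.
#' @param exposure_stats exposure summary statistics.
#' @param ld optional signed LD matrix.
#' @param name combined endpoint label (default `"GI"`).
#' @param variants variant ids to scan (default: all).
#' @param ... passed to [run_polygenic()].
#' @return Estimates data.frame; the combined-endpoint scan is attached as
#'   `attr(, "scan")`.
#' @export
run_combined_outcome <- function(cohort, members, exposure_stats, ld = NULL,
                                 name = "GI", variants = NULL, ...) {
  def <- outcome_def(name, members = members)
  sstats <- scan(cohort, def, variants = variants)
  out <- run_polygenic(exposure_stats, sstats, ld = ld, ...)
  attr(out, "scan") <- sstats
  out
}
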
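#' Outcome definition
#'
#' Encodes a cancer endpoint: optional sex restriction, the control scheme,
#' and optional member outcomes for combined endpoints (e.g. a
#' gastrointestinal endpoint combining liver, stomach, bowel, esophagus,
#' biliary tract and pancreas).
#'
#' Control schemes: `"all_noncase"` uses every non-case as a control (an
#' individual with a different cancer can be a control for another
#' cancer); `"exclude_other_cancers"` removes individuals with a different
#' cancer from the analysis entirely; `"exclude_selfreport_only"` removes
#' cases whose outcome is self-reported only.
#'
#' @param name outcome label; for a simple endpoint it must match a column
#'   of the cohort's outcome matrix.
#' @param sex_restriction `"none"`, `"female"` or `"male"`.
#' @param control_scheme one of the three schemes above.
#' @param members optional character vector (>= 2 distinct names) of member
#'   outcomes for a combined endpoint.
#' @return An object of class `outcome_def`.
#' @export
outcome_def <- function(name,
                        sex_restriction = c("none", "female", "male"),
                        control_scheme = c("all_noncase",
                                           "exclude_other_cancers",
                                           "exclude_selfreport_only"),
                        members = NULL) {
  sex_restriction <- match.arg(sex_restriction)
  control_scheme <- match.arg(control_scheme)
  if (!is.null(members)) {
    members <- unique(members)
    if (length(members) < 2L)
      stop("a combined endpoint needs at least 2 distinct member outcomes")
  }
  structure(list(name = name, sex_restriction = sex_restriction,
                 control_scheme = control_scheme, members = members),
            class = "outcome_def")
}

#' Define cases and the analysis mask for an outcome
#'
#' @param cohort a `cohort_data` object (or any list with `outcomes`,
#'   `any_cancer`, `selfreport_only` and `covariates$sex`).
#' @param def an [outcome_def].
#' @return list with logical vectors `case` (cases among all individuals)
#'   and `mask` (inclusion in the analysis). Cases of a combined endpoint
#'   are the union of the member case sets (an individual with two member
#'   cancers counts once).
#' @export
define_cases_controls <- function(cohort, def) {
  stopifnot(inherits(def, "outcome_def"))
  om <- cohort$outcomes
  if (is.null(def$members)) {
    if (!def$name %in% colnames(om))
      stop("unknown outcome: ", def$name)
    case <- om[, def$name] == 1L
  } else {
    miss <- setdiff(def$members, colnames(om))
    if (length(miss) > 0L)
      stop("unknown member outcome(s): ", paste(miss, collapse = ", "))
    case <- rowSums(om[, def$members, drop = FALSE]) > 0L
  }
  mask <- rep(TRUE, length(case))
  if (def$sex_restriction == "female") mask <- cohort$covariates$sex == 1L
  if (def$sex_restriction == "male") mask <- cohort$covariates$sex == 0L
  if (def$control_scheme == "exclude_other_cancers")
    mask <- mask & !(cohort$any_cancer & !case)
  if (def$control_scheme == "exclude_selfreport_only")
    mask <- mask & !(case & cohort$selfreport_only)
  if (sum(case & mask) == 0L)
    stop("no cases left for outcome '", def$name, "' after masking")
  if (sum(!case & mask) == 0L)
    stop("no controls left for outcome '", def$name, "' after masking")
  list(case = case, mask = mask)
}

#' Covariate-adjusted logistic regression for one variant
#'
#' Maximum-likelihood per-allele log-odds ratio by iteratively reweighted
#' least squares (via [stats::glm.fit]), SE from the observed information,
#' two-sided normal p-value. Convergence: relative deviance change below
#' `tol` (default 1e-8) within `max_iter` (default 50) iterations.
#' Separation (any fitted probability within 1e-8 of 0/1 together with a
#' diverging coefficient) is flagged rather than returned as a silent NaN.
#'
#' @param y 0/1 outcome vector.
#' @param dosage additive genotype dosage (0/1/2).
#' @param covariates optional data.frame/matrix of adjustment covariates.
#' @param max_iter,tol IRLS controls.
#' @return list with `beta`, `se`, `p`, `converged`, `separation`.
#' @export
fit_logistic <- function(y, dosage, covariates = NULL, max_iter = 50L,
                         tol = 1e-8) {
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("need at least one case and one control")
  if (var(dosage) == 0) stop("constant dosage")
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) {
    cm <- as.matrix(covariates)
    ok <- apply(cm, 2L, var) > 0
    X <- cbind(X, cm[, ok, drop = FALSE])
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = glm.control(epsilon = tol, maxit = max_iter)))
  p_rank <- fit$rank
  Rq <- fit$qr$qr[seq_len(p_rank), seq_len(p_rank), drop = FALSE]
  cov_mat <- chol2inv(Rq)
  idx <- which(fit$qr$pivot[seq_len(p_rank)] == 2L)
  if (length(idx) == 0L) stop("dosage dropped from fit (rank deficiency)")
  beta <- fit$coefficients[["dosage"]]
  se <- sqrt(cov_mat[idx, idx])
  mu <- fit$fitted.values
  separation <- (any(mu < 1e-8) || any(mu > 1 - 1e-8)) && abs(beta) > 10
  list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
       converged = fit$converged && !separation,
       separation = separation)
}

#' Association scan: outcome summary statistics for a variant set
#'
#' Runs [fit_logistic()] for every variant on the masked analysis sample
#' defined by the outcome's case/control scheme, with adjustment for age,
#' sex and the ten principal components (sex is dropped automatically for
#' sex-restricted outcomes, where it is constant).
#'
#' @param cohort a `cohort_data` object.
#' @param def an [outcome_def].
#' @param variants variant ids to scan (default: all).
#' @param adjust logical; include covariate adjustment (default `TRUE`).
#' @return A summary-statistics data.frame (log-odds scale) with one row
#'   per variant, the analysis sample size after masking in `n`, and the
#'   per-variant `converged`/`separation` flags carried as extra columns.
#' @export
scan <- function(cohort, def, variants = NULL, adjust = TRUE) {
  cc <- define_cases_controls(cohort, def)
  ids <- variants %||% colnames(cohort$genotypes)
  miss <- setdiff(ids, colnames(cohort$genotypes))
  if (length(miss) > 0L)
    stop("variants not in genotype matrix: ", paste(miss, collapse = ", "))
  m <- cc$mask
  y <- as.integer(cc$case[m])
  covs <- NULL
  if (adjust) {
    covs <- cohort$covariates[m, c("age", "sex", paste0("PC", 1:10))]
    if (def$sex_restriction != "none") covs$sex <- NULL
  }
  vi <- cohort$variant_info
  rows <- lapply(ids, function(v) {
    g <- cohort$genotypes[m, v]
    f <- fit_logistic(y, g, covs)
    i <- match(v, vi$variant_id)
    data.frame(variant_id = v, chr = vi$chr[i], pos = vi$pos[i],
               effect_allele = vi$effect_allele[i],
               other_allele = vi$other_allele[i],
               eaf = mean(g) / 2, beta = f$beta, se = f$se, pvalue = f$p,
               n = sum(m), trait = def$name,
               converged = f$converged, separation = f$separation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
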
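#' Percentage with presentation rounding
#'
#' `round(100 * count / denominator, 1)` — the one place percentages are
#' rounded; internal computations carry full precision.
#'
#' @param count,denominator nonnegative counts; `denominator > 0`.
#' @export
percent_of <- function(count, denominator) {
  stopifnot(all(denominator > 0))
  round(100 * count / denominator, 1)
}

#' Cohort descriptive table
#'
#' Case counts and percentages per outcome with the correct denominator:
#' for sex-restricted outcomes the percentage is of individuals of the
#' relevant sex. Continuous covariates are summarized as mean (SD) in
#' `attr(, "covariates")`.
#'
#' @param cohort a `cohort_data` object.
#' @param defs list of [outcome_def]s to tabulate.
#' @return data.frame with columns `label`, `count`, `denominator`,
#'   `percent`, `denominator_kind` (`"all"` or `"relevant_sex"`); zero-row
#'   for an empty cohort.
#' @export
build_cohort_table <- function(cohort, defs) {
  n <- nrow(cohort$outcomes)
  if (n == 0L) {
    return(data.frame(label = character(0), count = integer(0),
                      denominator = integer(0), percent = numeric(0),
                      denominator_kind = character(0),
                      stringsAsFactors = FALSE))
  }
  sex <- cohort$covariates$sex
  rows <- lapply(defs, function(def) {
    stopifnot(inherits(def, "outcome_def"))
    case <- if (is.null(def$members)) cohort$outcomes[, def$name] == 1L
      else rowSums(cohort$outcomes[, def$members, drop = FALSE]) > 0L
    if (def$sex_restriction == "none") {
      den <- n; kind <- "all"
    } else {
      den <- if (def$sex_restriction == "female") sum(sex == 1L)
        else sum(sex == 0L)
      kind <- "relevant_sex"
      case <- case & (if (def$sex_restriction == "female") sex == 1L
                      else sex == 0L)
    }
    data.frame(label = def$name, count = sum(case), denominator = den,
               percent = percent_of(sum(case), den),
               denominator_kind = kind, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  covs <- cohort$covariates[, c("age", "sex")]
  attr(out, "covariates") <- data.frame(
    covariate = c("age", "female_fraction"),
    mean = c(mean(covs$age), mean(covs$sex)),
    sd = c(sd(covs$age), sd(covs$sex)))
  rownames(out) <- NULL
  out
}

#' Cohort table from printed counts
#'
#' Builds the same table structure directly from reported counts and
#' denominators (for checking a published table's arithmetic).
#'
#' @param labels outcome labels.
#' @param counts case counts.
#' @param denominators denominators (total sample or relevant-sex count).
#' @param denominator_kind `"all"` or `"relevant_sex"` per row.
#' @export
cohort_table_from_counts <- function(labels, counts, denominators,
                                     denominator_kind = "all") {
  kind <- rep_len(denominator_kind, length(labels))
  bad <- setdiff(unique(kind), c("all", "relevant_sex"))
  if (length(bad) > 0L)
    stop("unknown denominator_kind: ", paste(bad, collapse = ", "))
  data.frame(label = labels, count = counts, denominator = denominators,
             percent = percent_of(counts, denominators),
             denominator_kind = kind, stringsAsFactors = FALSE)
}

#' Case-count range and median across site-specific outcomes
#'
#' @param table a cohort table (from [build_cohort_table()] or
#'   [cohort_table_from_counts()]); rows are site-specific outcomes.
#' @return list with `min`, `min_label`, `max`, `max_label`, and `median`
#'   (midpoint-averaged order statistic, rounded to the nearest integer
#'   for presentation).
#' @export
case_count_summary <- function(table) {
  stopifnot(nrow(table) >= 1L)
  cnt <- table$count
  list(min = min(cnt), min_label = table$label[which.min(cnt)],
       max = max(cnt), max_label = table$label[which.max(cnt)],
       median = round(median(cnt)))
}

#' Convert lipid concentrations from mg/dL to mmol/L
#'
#' Molar-mass conversion: divide by 38.67 for cholesterol fractions and by
#' 88.57 for triglycerides. Presentation rounding (1 decimal) is left to
#' the caller.
#'
#' @param value concentration(s) in mg/dL, nonnegative.
#' @param analyte `"cholesterol"` or `"triglycerides"`.
#' @return Concentration in mmol/L at full precision.
#' @export
mgdl_to_mmol <- function(value, analyte = c("cholesterol", "triglycerides")) {
  analyte <- match.arg(analyte)
  stopifnot(all(value >= 0))
  value / switch(analyte, cholesterol = 38.67, triglycerides = 88.57)
}

#' Reference standard deviations of the lipid fractions (mg/dL)
#'
#' Consortium-scale SDs used for unit annotations (estimation throughout
#' the package is in SD units): TC 45.6, LDL 39.0, HDL 15.8, TG 90.5.
#'
#' @return Named numeric vector.
#' @export
lipid_sd_mgdl <- function() {
  c(TC = 45.6, LDL = 39.0, HDL = 15.8, TG = 90.5)
}
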
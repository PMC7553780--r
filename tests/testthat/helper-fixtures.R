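# Shared fixtures: small harmonized datasets and toy cohorts built in code.

h_data <- function(bx, by, sy, sx = NULL, rho = NULL, ...) {
  bx <- as.matrix(bx)
  sx <- sx %||% (abs(bx) * 0 + 1e-4)
  lipidmr::harmonized_data(bx, as.matrix(sx), by, sy, rho, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random uncorrelated univariable instance with strong instruments
random_instance <- function(J = 10L) {
  bx <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE)
  sy <- runif(J, 0.01, 0.05)
  by <- rnorm(J, 0.3 * bx, sy)
  h_data(bx, by, sy, sx = rep(1e-4, J))
}

# exchangeable correlation matrix
exch_cor <- function(J, r) {
  m <- matrix(r, J, J); diag(m) <- 1; m
}

# minimal cohort-like list accepted by define_cases_controls /
# build_cohort_table
toy_cohort <- function(outcomes, sex, selfreport_only = NULL) {
  outcomes <- as.matrix(outcomes)
  n <- nrow(outcomes)
  list(outcomes = outcomes,
       any_cancer = rowSums(outcomes) > 0L,
       selfreport_only = selfreport_only %||% rep(FALSE, n),
       covariates = data.frame(age = rep(50, n), sex = sex))
}

# fast two-sample summary-level draw for calibration loops
quick_summary <- function(cfg, seed) lipidmr::sim_summary_stats(cfg, seed = seed)
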
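# Estimator contracts against independent oracles: closed-form Wald ratio,
# the textbook uncorrelated IVW formula, brute-force GLS with explicit
# matrix inversion, the OLS transform of MR-Egger, and direct enumeration
# of the weighted-median band-midpoint formula.

test_that("single-variant IVW is the Wald ratio", {
  h <- h_data(0.20, 0.10, 0.05)
  est <- ivw_correlated(h)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.25)
  expect_identical(est$n_variants, 1L)
})

test_that("IVW with identity LD equals the uncorrelated textbook formula", {
  set.seed(41)
  for (i in 1:200) {
    h <- random_instance(J = sample(3:15, 1L))
    est <- ivw_correlated(h, random_effects = FALSE)
    # independent oracle: ratio-estimate meta-analysis form
    r <- h$by / h$bx[, 1L]
    w <- h$bx[, 1L]^2 / h$sy^2
    expect_equal(est$beta, sum(w * r) / sum(w), tolerance = 1e-10)
    expect_equal(est$se, sqrt(1 / sum(w)), tolerance = 1e-10)
  }
})

test_that("correlated IVW matches a brute-force GLS oracle", {
  bx <- c(0.10, 0.20, 0.15)
  by <- c(0.05, 0.09, 0.08)
  sy <- c(0.01, 0.02, 0.015)
  rho <- exch_cor(3L, 0.3)
  h <- h_data(bx, by, sy, rho = rho)
  est <- ivw_correlated(h, random_effects = FALSE)
  # oracle: explicit inversion of Omega
  omega_inv <- solve(diag(sy) %*% rho %*% diag(sy))
  beta_oracle <- drop((t(bx) %*% omega_inv %*% by) /
                        (t(bx) %*% omega_inv %*% bx))
  se_oracle <- drop(sqrt(1 / (t(bx) %*% omega_inv %*% bx)))
  expect_equal(est$beta, beta_oracle, tolerance = 1e-10)
  expect_equal(est$se, se_oracle, tolerance = 1e-10)

  # random correlated instances
  set.seed(42)
  for (i in 1:50) {
    J <- sample(3:12, 1L)
    rho <- cov2cor(crossprod(matrix(rnorm(J * (J + 3L)), J + 3L, J)))
    bx <- runif(J, 0.05, 0.3)
    sy <- runif(J, 0.01, 0.05)
    by <- rnorm(J, 0.2 * bx, sy)
    h <- h_data(bx, by, sy, rho = rho)
    est <- ivw_correlated(h, random_effects = FALSE)
    oi <- solve(diag(sy) %*% rho %*% diag(sy))
    expect_equal(est$beta,
                 drop((t(bx) %*% oi %*% by) / (t(bx) %*% oi %*% bx)),
                 tolerance = 1e-8)
  }
})

test_that("random-effects SE never beats fixed-effect; equality iff Q <= df", {
  set.seed(43)
  for (i in 1:100) {
    h <- random_instance(J = 8L)
    fe <- ivw_correlated(h, random_effects = FALSE)
    re <- ivw_correlated(h, random_effects = TRUE)
    expect_gte(re$se, fe$se)
    if (re$Q <= re$df_Q) expect_equal(re$se, fe$se) else
      expect_gt(re$se, fe$se)
    expect_true(re$I2 >= 0 && re$I2 <= 100)
    expect_gte(re$re_scale, 1)
  }
})

test_that("multivariable IVW reduces exactly to univariable at one exposure", {
  set.seed(44)
  for (i in 1:20) {
    h <- random_instance(J = 10L)
    uni <- ivw_correlated(h, random_effects = TRUE)
    mv <- mvmr_ivw(h, random_effects = TRUE)[[1L]]
    expect_equal(mv$beta, uni$beta, tolerance = 1e-12)
    expect_equal(mv$se, uni$se, tolerance = 1e-12)
    expect_equal(mv$Q, uni$Q, tolerance = 1e-12)
  }
})

test_that("multivariable IVW on orthogonal exposure blocks equals separate fits", {
  set.seed(45)
  bx1 <- c(runif(4, 0.1, 0.3), rep(0, 4))
  bx2 <- c(rep(0, 4), runif(4, 0.1, 0.3))
  sy <- runif(8, 0.01, 0.04)
  by <- rnorm(8, 0.4 * bx1 - 0.2 * bx2, sy)
  h <- h_data(cbind(e1 = bx1, e2 = bx2), by, sy)
  mv <- mvmr_ivw(h, random_effects = FALSE)
  f1 <- ivw_correlated(h_data(bx1[1:4], by[1:4], sy[1:4]),
                       random_effects = FALSE)
  f2 <- ivw_correlated(h_data(bx2[5:8], by[5:8], sy[5:8]),
                       random_effects = FALSE)
  expect_equal(mv$e1$beta, f1$beta, tolerance = 1e-10)
  expect_equal(mv$e2$beta, f2$beta, tolerance = 1e-10)
  expect_equal(mv$e1$se, f1$se, tolerance = 1e-10)
})

test_that("collinear exposures are rejected with their names", {
  bx <- runif(6, 0.1, 0.3)
  h <- h_data(cbind(LDL = bx, TC = 2 * bx), rnorm(6, 0, 0.02),
              rep(0.02, 6))
  expect_error(mvmr_ivw(h), "collinear")
})

test_that("MR-Egger recovers an exact linear relation to machine precision", {
  bx <- c(0.08, 0.12, 0.2, 0.25, 0.3)
  by <- 0.013 + 0.6 * bx   # exact: intercept 0.013, slope 0.6
  h <- h_data(bx, by, runif(5, 0.01, 0.03))
  est <- mr_egger(h, random_effects = FALSE)
  expect_equal(est$beta, 0.6, tolerance = 1e-12)
  expect_equal(est$intercept, 0.013, tolerance = 1e-12)
  expect_equal(est$Q, 0, tolerance = 1e-18)
})

test_that("MR-Egger with identity LD matches the weighted-OLS oracle", {
  set.seed(46)
  for (i in 1:20) {
    J <- 8L
    bx <- runif(J, 0.05, 0.3)
    sy <- runif(J, 0.01, 0.05)
    by <- rnorm(J, 0.01 + 0.3 * bx, sy)
    h <- h_data(bx, by, sy)
    est <- mr_egger(h, random_effects = FALSE)
    # oracle: divide through by sy and run ordinary least squares
    fit <- lm(I(by / sy) ~ 0 + I(1 / sy) + I(bx / sy))
    expect_equal(est$intercept, unname(coef(fit)[1L]), tolerance = 1e-8)
    expect_equal(est$beta, unname(coef(fit)[2L]), tolerance = 1e-8)
    sm <- summary(fit)
    # lm scales the covariance by its residual variance; undo for the
    # fixed-effect (sigma = 1) convention
    expect_equal(est$se, unname(sm$coefficients[2L, 2L] / sm$sigma),
                 tolerance = 1e-8)
  }
})

test_that("MR-Egger is invariant to input row sign flips", {
  set.seed(47)
  bx <- runif(7, 0.05, 0.3)
  sy <- runif(7, 0.01, 0.05)
  by <- rnorm(7, 0.02 + 0.4 * bx, sy)
  rho <- cov2cor(crossprod(matrix(rnorm(70), 10, 7)))
  h <- h_data(bx, by, sy, rho = rho)
  ref <- mr_egger(h)
  for (i in 1:5) {
    s <- sample(c(-1, 1), 7, replace = TRUE)
    hf <- h_data(bx * s, by * s, sy, rho = rho * outer(s, s))
    est <- mr_egger(hf)
    expect_equal(est$beta, ref$beta, tolerance = 1e-10)
    expect_equal(est$intercept, ref$intercept, tolerance = 1e-10)
    expect_equal(est$se, ref$se, tolerance = 1e-10)
  }
})

test_that("weighted median handles degenerate and textbook cases", {
  # all ratios identical
  bx <- rep(0.2, 4); by <- 0.4 * bx
  h <- h_data(bx, by, rep(0.02, 4))
  expect_equal(weighted_median(h, n_boot = 50L)$beta, 0.4)
  # equal weights, middle order statistic
  bx <- rep(0.2, 3)
  h <- h_data(bx, bx * c(0.1, 0.5, 0.9), rep(0.02, 3))
  expect_equal(weighted_median(h, n_boot = 50L)$beta, 0.5)
  # 4 variants, weights 1:1:1:3 -> band-midpoint interpolation
  sy <- c(1, 1, 1, 1 / sqrt(3)) * 0.02  # w propto bx^2/sy^2 = (1,1,1,3)
  bx <- rep(0.2, 4)
  h <- h_data(bx, bx * c(0.1, 0.2, 0.3, 0.8), sy)
  expect_equal(weighted_median(h, n_boot = 50L)$beta, 0.425)
})

test_that("weighted median matches an enumeration oracle on random input", {
  # independent oracle: explicit band-midpoint formula
  oracle <- function(r, w) {
    o <- order(r); r <- r[o]; w <- w[o] / sum(w)
    mid <- cumsum(w) - w / 2
    if (0.5 <= mid[1L]) return(r[1L])
    k <- max(which(mid < 0.5))
    if (k == length(r)) return(r[length(r)])
    r[k] + (r[k + 1L] - r[k]) * (0.5 - mid[k]) / (mid[k + 1L] - mid[k])
  }
  set.seed(48)
  for (i in 1:100) {
    J <- sample(3:12, 1L)
    bx <- runif(J, 0.05, 0.4)
    sy <- runif(J, 0.01, 0.08)
    by <- rnorm(J, 0.2 * bx, sy)
    h <- h_data(bx, by, sy)
    est <- weighted_median(h, n_boot = 10L)
    expect_equal(est$beta, oracle(by / bx, bx^2 / sy^2), tolerance = 1e-12)
    expect_gte(est$beta, min(by / bx))
    expect_lte(est$beta, max(by / bx))
  }
})

test_that("weighted median rejects zero exposure associations; bootstrap seed is recorded", {
  h <- h_data(c(0.2, 0, 0.3), c(0.1, 0.1, 0.1), rep(0.02, 3))
  expect_error(weighted_median(h), "var_002")
  h2 <- random_instance(6L)
  est <- weighted_median(h2, n_boot = 100L, seed = 7L)
  expect_identical(est$flags$boot_seed, 7L)
  # same seed, same SE
  expect_equal(weighted_median(h2, n_boot = 100L, seed = 7L)$se, est$se)
})

test_that("pruning keeps the stronger variant and returns valid sets", {
  # identity LD: nothing removed
  h <- random_instance(6L)
  expect_identical(prune_correlated(h, 0.4)$variants, h$variants)

  # one correlated pair: keep the smaller exposure p-value
  rho <- exch_cor(2L, sqrt(0.5))
  h2 <- h_data(c(0.3, 0.1), c(0.1, 0.05), c(0.02, 0.02),
               sx = c(0.02, 0.02), rho = rho)  # variant 1 has smaller p
  pr <- prune_correlated(h2, 0.4)
  expect_identical(pr$variants, "var_001")

  # chain A-B-C: result depends on p-values, validated by exhaustive search
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- sqrt(0.5)
  rho[2, 3] <- rho[3, 2] <- sqrt(0.5)
  mk <- function(z) h_data(z * 0.02, c(0.1, 0.1, 0.1), rep(0.02, 3),
                           sx = rep(0.02, 3), rho = rho)
  # A strongest, C middling, B weakest -> drop B, keep {A, C}
  prAC <- prune_correlated(mk(c(8, 4, 6)), 0.5)
  expect_setequal(prAC$variants, c("var_001", "var_003"))
  # B strongest -> B survives both pairs, A and C dropped
  prB <- prune_correlated(mk(c(4, 8, 5)), 0.5)
  expect_identical(prB$variants, "var_002")

  # property: pruned sets never contain an offending pair
  set.seed(49)
  for (i in 1:30) {
    J <- sample(4:10, 1L)
    rho <- cov2cor(crossprod(matrix(rnorm(J * (J + 1L)), J + 1L, J)))
    h3 <- h_data(runif(J, 0.05, 0.3), rnorm(J, 0, 0.05),
                 runif(J, 0.01, 0.05), sx = rep(0.02, J), rho = rho)
    pr3 <- prune_correlated(h3, 0.3)
    r2 <- pr3$rho^2; diag(r2) <- 0
    expect_lt(max(r2, 0), 0.3)
  }
})

test_that("Cochran's Q matches hand arithmetic and the GLS quadratic form", {
  # w = (100, 100), ratios (0.2, 0.6), beta 0.4 -> Q = 8, I2 = 87.5
  h <- h_data(c(1, 1), c(0.2, 0.6), c(0.1, 0.1))
  q <- cochran_q(h, 0.4)
  expect_equal(q$Q, 8)
  expect_equal(q$I2, 87.5)
  expect_equal(q$df, 1L)
  # identical ratios -> zero heterogeneity
  h0 <- h_data(c(0.1, 0.2), c(0.04, 0.08), c(0.01, 0.01))
  q0 <- cochran_q(h0, 0.4)
  expect_equal(q0$Q, 0, tolerance = 1e-20)
  expect_equal(q0$I2, 0)
})

test_that("direction inversion reproduces the reciprocal-OR worked example", {
  est <- mr_estimate_from_or(1.32, 1.13, 1.53, p = 3e-4)
  inv <- invert_direction(est)
  expect_equal(round(inv$or, 2), 0.76)
  expect_equal(round(inv$or_lower, 2), 0.65)
  expect_equal(round(inv$or_upper, 2), 0.88)
  expect_equal(inv$p, est$p)
  # identity at OR 1
  e1 <- mr_estimate_from_or(1.00, 0.9, 1 / 0.9)
  expect_equal(invert_direction(e1)$or, 1.00, tolerance = 1e-12)
  # involution
  back <- invert_direction(inv)
  expect_equal(back$beta, est$beta)
  expect_equal(back$or_lower, est$or_lower)
  expect_equal(back$or_upper, est$or_upper)
})

test_that("estimate container keeps CI/OR consistent", {
  est <- mr_estimate("IVW", beta = 0.3, se = 0.1)
  expect_equal(est$ci_lower, 0.3 - qnorm(0.975) * 0.1)
  expect_equal(est$or_lower, exp(est$ci_lower))
  expect_equal(est$or_upper, exp(est$ci_upper))
})
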
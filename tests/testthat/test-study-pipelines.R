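# Pipeline orchestration: scaling conventions, region validation, robust
# follow-up, combined endpoints, and the drug-target vs polygenic contrast.

test_that("region specs enforce scaling traits and the r2 rule", {
  expect_error(region_spec("HMGCR", "v1", scaling_trait = "TG"), "LDL")
  expect_error(region_spec("BRCA1", "v1"), "unknown gene region")
  ld <- exch_cor(2L, 0.8)
  dimnames(ld) <- list(c("v1", "v2"), c("v1", "v2"))
  expect_error(region_spec("HMGCR", c("v1", "v2"), ld = ld), "r2 < 0.4")
  reg <- region_spec("APOC3", c("v1", "v2"),
                     ld = diag(2) |> `dimnames<-`(dimnames(ld)))
  expect_identical(reg$scaling_trait, "TG")
  # registry ships the declared variance-explained values
  registry <- gene_region_registry()
  expect_setequal(registry$gene,
                  c("HMGCR", "PCSK9", "LDLR", "NPC1L1", "APOC3", "LPL"))
  expect_equal(registry$variance_explained_ldl[registry$gene == "HMGCR"],
               0.004)
})

test_that("rescaling exposure units rescales the causal estimate exactly", {
  cfg <- sim_config(seed = 51L, n_variants = 10L, ld_decay = 0.3,
                    n_exposure_sample = 20000L, n_outcome_sample = 20000L,
                    causal_effects = c(LDL = 0.3, HDL = 0, TG = 0),
                    case_fraction = 0.2)
  ss <- sim_summary_stats(cfg)
  h <- harmonize(ss$exposure, ss$outcome, ld = ss$ld, exposures = "LDL")
  base <- ivw_correlated(h)
  c_scale <- 2.5
  h2 <- h
  h2$bx <- h$bx * c_scale
  h2$sx <- h$sx * c_scale
  scaled <- ivw_correlated(h2)
  expect_equal(scaled$beta, base$beta / c_scale, tolerance = 1e-12)
  expect_equal(scaled$se, base$se / c_scale, tolerance = 1e-12)
})

test_that("gene-region pipeline runs the correlated IVW on the scaling trait", {
  cfg <- sim_config(seed = 52L, n_variants = 5L, ld_decay = 0.4,
                    n_exposure_sample = 50000L, n_outcome_sample = 50000L,
                    causal_effects = c(LDL = log(1.5), HDL = 0, TG = 0),
                    case_fraction = 0.2,
                    target_r2 = c(LDL = 0.004, HDL = 0.002, TG = 0.002))
  ss <- sim_summary_stats(cfg)
  reg <- region_spec("HMGCR", cfg$variant_ids, variance_explained = 0.004)
  est <- run_gene_region(reg, ss$exposure, ss$outcome, ss$ld)
  expect_identical(est$exposure, "LDL")
  expect_identical(est$flags$gene, "HMGCR")
  expect_lt(abs(est$beta - log(1.5)) / est$se, 4)
  # missing variants are reported by id
  expect_error(run_gene_region(region_spec("HMGCR", c("nope", "v?")),
                               ss$exposure, ss$outcome, ss$ld), "nope")
})

test_that("polygenic pipeline fits MVMR for subfractions and univariable for TC", {
  cfg <- sim_config(seed = 53L, n_variants = 40L,
                    n_exposure_sample = 50000L, n_outcome_sample = 50000L,
                    causal_effects = c(LDL = log(1.3), HDL = 0, TG = 0),
                    case_fraction = 0.2)
  ss <- sim_summary_stats(cfg)
  tab <- run_polygenic(ss$exposure, ss$outcome, ld = ss$ld)
  expect_setequal(tab$exposure, c("LDL", "HDL", "TG", "TC"))
  expect_true(all(grepl("MVMR", tab$method[tab$exposure != "TC"])))
  expect_false(grepl("MVMR", tab$method[tab$exposure == "TC"]))
  expect_true(all(is.finite(tab$Q)))
  # deterministic on fixed input
  expect_identical(tab, run_polygenic(ss$exposure, ss$outcome, ld = ss$ld))
  # single-exposure input degrades to a univariable analysis
  uni <- run_polygenic(ss$exposure[ss$exposure$trait == "LDL", ],
                       ss$outcome, ld = ss$ld, tc_trait = NULL)
  expect_equal(nrow(uni), 1L)
  expect_match(uni$method, "^IVW")
})

test_that("a TC-mediated effect is recovered by the univariable TC analysis", {
  cfg0 <- sim_config(seed = 54L, n_variants = 60L,
                     n_exposure_sample = 100000L,
                     n_outcome_sample = 100000L, case_fraction = 0.2)
  theta_tc <- log(1.18)
  cfg <- sim_config(seed = 54L, n_variants = 60L,
                    n_exposure_sample = 100000L, n_outcome_sample = 100000L,
                    case_fraction = 0.2,
                    causal_effects = causal_via_tc(cfg0, theta_tc))
  ss <- sim_summary_stats(cfg)
  tab <- run_polygenic(ss$exposure, ss$outcome, ld = ss$ld)
  tc <- tab[tab$exposure == "TC", ]
  expect_lt(abs(tc$beta - theta_tc) / tc$se, 4)
})

test_that("robust follow-up appends Egger and weighted-median rows and flags attenuation", {
  # directional pleiotropy, no causal effect: IVW is biased away from zero,
  # MR-Egger absorbs the bias into its intercept. Instruments all carry
  # genuine LDL effects (as significance-selected instruments do), so the
  # sign orientation is unambiguous.
  set.seed(550)
  eff <- cbind(LDL = runif(50, 0.03, 0.3) * sample(c(-1, 1), 50, TRUE),
               HDL = rnorm(50, 0, 0.02), TG = rnorm(50, 0, 0.02))
  cfg <- sim_config(seed = 55L, n_variants = 50L, exposure_effects = eff,
                    n_exposure_sample = 100000L, n_outcome_sample = 100000L,
                    case_fraction = 0.2, pleiotropy_mode = "directional",
                    pleiotropy_sd = 0.003, pleiotropy_mean = 0.012)
  ss <- sim_summary_stats(cfg, seed = 57L)
  tab <- run_polygenic(ss$exposure, ss$outcome, ld = ss$ld)
  expect_lt(tab$p[tab$exposure == "LDL"], 0.01)
  ext <- robust_followup(tab, ss$exposure, ss$outcome, ld = ss$ld,
                         threshold = 0.01, n_boot = 200L)
  expect_gt(nrow(ext), nrow(tab))
  added <- ext[!is.na(ext$followup_of), ]
  expect_true(any(grepl("Egger", added$method)))
  expect_true(any(added$method == "Weighted median"))
  expect_true(any(added$attenuated[grepl("MR-Egger", added$method)]))
  # nothing significant -> table unchanged
  null_tab <- tab
  null_tab$p <- 0.5
  ext0 <- robust_followup(null_tab, ss$exposure, ss$outcome, ld = ss$ld)
  expect_equal(nrow(ext0), nrow(null_tab))
})

test_that("combined endpoints pool member cases once and re-scan", {
  cfg <- sim_config(seed = 56L, n_variants = 8L, case_fraction = 0.05,
                    outcomes = list(
                      liver = list(case_fraction = 0.03),
                      bowel = list(case_fraction = 0.05),
                      lung = list(case_fraction = 0.04)))
  co <- simulate_cohort(cfg, n = 4000L)
  es_cfg <- sim_summary_stats(cfg)
  out <- run_combined_outcome(co, c("liver", "bowel"), es_cfg$exposure,
                              ld = es_cfg$ld)
  sc <- attr(out, "scan")
  expect_true(all(sc$trait == "GI"))
  union_cases <- sum(rowSums(co$outcomes[, c("liver", "bowel")]) > 0)
  both <- sum(rowSums(co$outcomes[, c("liver", "bowel")]) == 2)
  expect_equal(union_cases,
               sum(co$outcomes[, "liver"]) + sum(co$outcomes[, "bowel"]) - both)
  expect_setequal(out$exposure, c("LDL", "HDL", "TG", "TC"))
})

test_that("purely lipid-mediated effects give matching region and polygenic estimates", {
  cfg <- sim_config(seed = 57L, n_variants = 30L,
                    n_exposure_sample = 100000L, n_outcome_sample = 200000L,
                    causal_effects = c(LDL = log(1.3), HDL = 0, TG = 0),
                    case_fraction = 0.2)
  ss <- sim_summary_stats(cfg)
  reg <- region_spec("HMGCR", cfg$variant_ids[1:5])
  est_reg <- run_gene_region(reg, ss$exposure, ss$outcome, ss$ld)
  tab <- run_polygenic(ss$exposure, ss$outcome, ld = ss$ld)
  ldl <- tab[tab$exposure == "LDL", ]
  pooled_se <- sqrt(est_reg$se^2 + ldl$se^2)
  expect_lt(abs(est_reg$beta - ldl$beta) / pooled_se, 4)
})
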
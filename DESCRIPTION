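Package: lipidmr
Title: Two-Sample Mendelian Randomization of Lipid Fractions and
    Lipid-Lowering Drug Targets on Cancer Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) of blood
    lipid fractions and drug-target gene-region proxies on binary cancer
    outcomes.  Implements the inverse-variance weighted estimator with
    correlated variants (generalized weighted linear regression),
    multivariable MR for lipid subfractions, MR-Egger (univariable and
    multivariable), the weighted median estimator with bootstrap standard
    errors, LD-based variant pruning, Cochran's Q and Higgins' I-squared
    heterogeneity statistics, and asymptotic power calculations for
    binary-outcome MR.  A synthetic-data module generates individual-level
    cohorts (autoregressive LD with a closed-form signed correlation
    matrix, multi-trait lipid effects, logistic outcomes with configurable
    pleiotropy) and matching summary statistics, so the full analysis
    pipeline -- covariate-adjusted logistic association scans, gene-region
    drug-proxy analyses, polygenic multivariable analyses, robust-method
    follow-up and combined endpoints -- can be exercised end to end
    without access to individual-level biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
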
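---
title: "Methods: estimators, generative model, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators, generative model, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmr)
```

# The estimation problem

Two-sample Mendelian randomization takes per-variant associations with an
exposure (here: blood lipid fractions, in SD units, from a large lipid
consortium scan) from one sample and per-variant associations with a binary
outcome (cancer endpoints, log-odds from covariate-adjusted logistic
regression) from a second, non-overlapping sample. Under the instrumental
variable assumptions — each variant is associated with the exposure,
independent of confounders, and affects the outcome only through the
exposure — the ratio `b_Yj / b_Xj` estimates the causal log odds ratio per
SD of exposure, and the estimators below pool these ratios.

## IVW with correlated variants

`ivw_correlated()` fits generalized weighted least squares of `b_Y` on
`b_X` without intercept, with covariance
`Omega = diag(s_Y) %*% rho %*% diag(s_Y)` where `rho` is the *signed* LD
correlation matrix of effect-allele dosages:

```
beta = (b_X' Omega^-1 b_X)^-1 b_X' Omega^-1 b_Y
var_FE(beta) = (b_X' Omega^-1 b_X)^-1
```

With `rho = I` this reduces to the familiar
`sum(w r) / sum(w)` over ratio estimates with `w = b_X^2 / s_Y^2`; with one
variant it is the Wald ratio. Drug-target gene regions (few, partially
correlated variants chosen from conditional analyses with pairwise
r² < 0.4) are the motivating case for the correlated form.

**Random effects.** All pipeline fits use the multiplicative
random-effects model: the fixed-effect SE is scaled by
`max(1, sqrt(Q / df))`, where `Q` is the GLS residual quadratic form and
`df = J - K`. The floor at 1 means random-effects precision never beats
fixed-effect precision; under no heterogeneity the estimator is slightly
conservative (measured type-I error ≈ 0.03–0.05 at nominal 0.05), which is
the accepted trade-off of this convention.

**Numerical handling of `Omega`.** If the smallest eigenvalue is below
`1e-8` times the largest (near-duplicate variants), a ridge of
`1e-8 * trace/J` is added with a warning; if the Cholesky factorization
still fails the error names the worst-correlated variant pair. Solves go
through the Cholesky factor rather than explicit inversion.

## Multivariable IVW

`mvmr_ivw()` regresses `b_Y` jointly on all exposure columns (LDL, HDL,
triglycerides), giving each fraction's direct effect conditional on the
others; rank deficiency is reported with the offending trait names. With a
single exposure it reduces *exactly* to the univariable fit (asserted in
the tests). Total cholesterol is analysed univariably, since it is (by
construction, see below) a linear combination of the subfractions and
would be collinear in the joint model.

## MR-Egger

`mr_egger()` / `mvmr_egger()` add a free intercept to the same GLS; the
intercept estimates average directional pleiotropy and the slope is the
pleiotropy-adjusted effect (valid under the assumption that pleiotropic
effects are independent of instrument strength). Variants are first
oriented so the exposure of interest has non-negative associations; an
orientation flip negates a variant's exposure and outcome betas *and* its
row/column of the signed LD matrix, which makes the fit invariant to the
input orientation (a property test asserts this). A near-zero spread of
the exposure associations leaves the slope unidentified and is flagged
(`flags$unstable`), not silently returned.

A genuine limitation, documented rather than patched: instruments with
(near-)zero exposure effect get randomly sign-oriented, which dilutes the
recovered intercept and can bias the slope. Significance-selected
instrument sets do not contain such variants, and the calibration scenario
(`egger_scenario()`) therefore uses instruments whose LDL effects are all
nonzero.

## Weighted median

`weighted_median()` orders the per-variant ratios, normalizes the weights
`w = b_X^2 / s_Y^2`, and interpolates the ordered ratios at cumulative
weight 0.5 using band midpoints `p_j = cumsum(w)_j - w_j / 2`; it is
consistent when at least half the weight comes from valid instruments. The
estimator assumes uncorrelated variants, so the pipeline drops one of each
correlated pair first (`prune_correlated()`, threshold r² ≥ 0.4; the
variant with the smaller exposure p-value is kept, ties broken by genomic
position, tied pairs resolved in storage order — all deterministic). The
SE is a parametric bootstrap (default 1,000 resamples of `(b_X, b_Y)` from
their normal sampling distributions; the seed is recorded in the output)
because no exact closed form exists.

## Heterogeneity and presentation

`cochran_q()` returns the GLS quadratic form (identical to the classic
`sum(w (r - beta)^2)` when `rho = I`), `I² = max(0, (Q - df)/Q) * 100`, and
a chi-square p-value. All estimates carry normal 95% CIs
(`beta ± 1.96 SE`) and exponentiated OR-scale equivalents;
`invert_direction()` re-expresses an estimate per SD *decrease*
(reciprocal OR, reciprocated-and-swapped CI, unchanged p). Rounding to
presentation precision (2 dp ORs, 1 dp percents) happens only in
formatting helpers; all internal computation keeps full precision.

# The synthetic cohort generator

`sim_config()` fixes the generative model; identical `(seed, config)` give
bit-identical output, with every derived quantity drawn from seeds derived
deterministically from the base seed.

**Genotypes.** Each haplotype's alleles come from a latent Gaussian AR(1)
process with autocorrelation `ld_decay^|i-j|`, thresholded at each
variant's MAF quantile; dosages are sums of two independent haplotypes.
The point of this model is that the implied signed dosage LD matrix is
available in closed form (`true_ld_matrix()`, via bivariate-normal orthant
probabilities computed by one-dimensional quadrature to relative tolerance
1e-10), so estimator tests work against a *known* `rho` instead of an
estimate. The default `ld_decay = 0` (independent variants) reflects the
polygenic instrument list; gene-region scenarios use positive decay.

**Lipids.** Each subfraction is `genotypes %*% effects` plus correlated
Gaussian noise scaled for unit total variance, then standardized
(mirroring rank-normalized consortium phenotypes). Default effect matrices
are sparse (each variant affects a random subset of fractions) and scaled
so the variance explained matches the study values: 14.6% (LDL), 13.7%
(HDL), 11.7% (triglycerides) for 184 variants. Total cholesterol is the
deterministic combination `LDL + 0.4 HDL + 0.45 TG` of the standardized
fractions, rescaled to unit variance — weights are configurable; the
source study treats TC as a separately analysed trait without stating its
generative relation, so a fixed positive combination was chosen to make
univariable TC and multivariable subfraction analyses simultaneously
meaningful (`causal_via_tc()` converts a TC-level causal effect into the
equivalent subfraction vector). The residual correlations between
fractions default to LDL–HDL −0.1, LDL–TG 0.2, HDL–TG −0.4 — plausible
epidemiological values, configurable and not calibrated to any dataset,
since the consortium phenotype covariance is not published.

**Outcome.** `P(case) = plogis(alpha + lipids %*% theta + pleiotropy +
covariates)`; the intercept is solved by bisection so the marginal case
fraction hits the configured `K` (to 1e-6; an unattainable `K` raises an
error reporting the achievable range). Covariates are age ~ U(40, 70)
years (log-OR 0.02/year by default), sex ~ Bernoulli(0.541 female, log-OR
−0.1), and ten standard-normal principal components — enough to exercise
the adjustment path, with no demographic realism claims. Pleiotropy modes:

* `balanced` — per-variant direct effects ~ N(0, `pleiotropy_sd`);
* `directional` — mean `pleiotropy_mean` applied to each variant's
  LDL-*raising* allele (the MR-Egger orientation convention; a fixed-sign
  per-allele mean would cancel across sign-symmetric exposure effects and
  bias nothing);
* `non_lipid_pathway` — a designated variant set (the drug-target region)
  receives a direct per-allele effect independent of lipid levels: the
  headline mechanism in which a statin-target region affects cancer while
  polygenic lipid effects are null.

**Two samples and the summary-level fast path.** `make_two_samples()`
draws two disjoint cohorts with shared frequencies/LD and independent
noise. For replicate-heavy calibration, `sim_summary_stats()` draws the
summary statistics directly from their asymptotic sampling distributions
(exposure SE `1/(sigma_j sqrt(n1))`, outcome SE
`1/(sigma_j sqrt(n2 K (1-K)))` with `sigma_j = sqrt(2 p_j (1-p_j))`,
errors correlated across variants by `rho` within each sample,
conditional effects marginalized through `D^-1 rho D`). The two paths are
cross-checked for agreement in the unit suite at n = 30,000. The
summary-level path ignores logistic non-collapsibility (its outcome truth
is the linear formula `gamma = B theta + delta`), which is negligible at
the per-allele effect sizes simulated here but would matter for very
strong single-variant effects.

**What passing tests do and do not show.** The generator reproduces the
statistical *structure* the estimators assume — two-sample independence,
known LD, unit-variance phenotypes, configured case fractions and
pleiotropy. It does not emulate health-record coding, survival/censoring,
biobank sampling design, population stratification, or assortative mating;
calibration results here say nothing about those threats in real data.

# Study pipelines and conditions

`run_gene_region()` validates the region (canonical scaling trait —
LDL-cholesterol for *HMGCR*/*PCSK9*/*LDLR*/*NPC1L1*, triglycerides for
*APOC3*/*LPL* — and pairwise r² < 0.4 against the supplied LD), harmonizes
the region variants and fits the random-effects correlated IVW.
`run_polygenic()` fits MVMR for the subfractions plus univariable TC.
`robust_followup()` appends MR-Egger (univariable and multivariable) and
the post-pruning weighted median for every estimate with p < 0.01 (the
threshold is the study's own reporting line, configurable), flagging
attenuation when a robust estimate flips sign or shrinks by more than half.
`run_combined_outcome()` unions member case sets (a person with two member
cancers counts once) and re-scans — the gastrointestinal endpoint pattern.

The named scenarios pin the study conditions once: exposure sample
188,577; outcome sample 367,703 with case fraction 0.204; 184 polygenic
variants; a 5-variant drug-target region explaining 0.4% of LDL variance.
In `headline_scenario()` the region carries a direct (non-lipid) effect of
log(1.32) per SD LDL while all lipid causal effects are zero. The region
list is *separate from* the 184 polygenic variants, mirroring the distinct
conditional-analysis selection of drug-target proxies; when the region is
instead embedded in the polygenic set, its direct effect leaks about
OR 1.008 of bias into the polygenic LDL estimate — structurally
interesting, but the separate-set design is the cleaner representation of
the mechanism and is the default.

## Power

`mr_power()` uses the standard asymptotic approximation for binary
outcomes: the causal log-OR estimate is normal with SE
`1/sqrt(n r2 K(1-K))`. The implementation keeps *both* tails of the
two-sided rejection region, so power equals `alpha` exactly at OR = 1 and
the formula remains a proper two-sided power everywhere;
`detectable_or()` inverts it by Newton iteration from the one-tail
closed-form start, making the power/detectable-OR round trip exact to
~1e-14. Closed-form power agrees with the empirical rejection rate of the
fixed-effect IVW pipeline to within 0.02 across a 3×3 grid of
(n ∈ {50k, 100k, 200k}) × (OR ∈ {1.05, 1.1, 1.15}) at r² = 0.05, K = 0.2
(3,000 replicates per cell in the acceptance suite). The random-effects
variant is slightly conservative, so its empirical power sits marginally
below the formula; the fixed-effect fit is the one the formula describes.

# Problem sizes and numerical settings

Calibration studies run at summary-statistic level so that hundreds of
replicates at the full study sample sizes stay cheap: 500 null replicates
(J = 30) for type-I error, 200 replicates (J = 184) for CI coverage under
a true LDL effect of log(1.2), 200 replicates each for the MR-Egger
intercept under balanced/directional pleiotropy (J = 60), 3,000 replicates
per power-grid cell (J = 15), and 400 replicates of the headline scenario
(J = 189). Individual-level simulation backs the association-scan tests
(n up to 200,000 for the single-variant variance-explained check, which
verifies the closed-form `r² = 2p(1-p) beta²`).

Logistic scans use IRLS (`stats::glm`) with relative tolerance 1e-8 and at
most 50 iterations; separation (a fitted probability within 1e-8 of 0/1
with a diverging coefficient) is flagged per variant, never silently
propagated. Harmonization aligns alleles by letter match with complement
(strand) handling; palindromic variants are resolved by allele frequency
when both frequencies are outside 0.5 ± 0.08 and dropped otherwise
(policy configurable: always-drop or same-strand-assume).

# Known limitations

* The weighted-median SE is a bootstrap; its p-values are approximate
  (measured type-I error ≈ 0.03–0.04 at nominal 0.05).
* The multiplicative random-effects model mis-weights when per-variant
  heterogeneity is additive and outcome SEs vary strongly; intercept
  coverage in the balanced-pleiotropy scenario measures ≈ 94–96%.
* Summary-level simulation treats the logistic marginal effect as linear
  in the lipid effects (no non-collapsibility).
* Gene-region variant lists are study-specific configuration, not shipped
  data; the registry carries only scaling traits and declared
  variance-explained values.
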
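---
title: "Methods: set-based gene-environment interaction scans with predicted expression"
author: "folategxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: set-based gene-environment interaction scans with predicted expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Folate intake is inversely associated with colorectal cancer risk in
observational studies, and folate metabolism touches DNA synthesis,
methylation and repair. Whether common genetic variation *modifies* the
folate association is a gene-environment (G x E) question. Testing each
variant separately against an exposure is underpowered; aggregating the
variants that regulate one gene's expression into a single set-based
test both raises power and points at an interpretable biological unit.
This package implements that analysis end to end for pooled
case-control consortia: exposure harmonization, genetically predicted
expression (GReX) from PrediXcan-style weight sets, a two-component
mixed-effects score test per gene, genome-scan multiple-testing
control, and the follow-up models that characterize flagged genes.

# Exposure harmonization

Total folate is expressed in dietary folate equivalents,

    DFE (mcg/day) = dietary folate + 1.7 x supplemental folic acid,

the 1.7 factor reflecting the higher bioavailability of synthetic folic
acid. Studies that recorded supplement use only as a yes/no flag have
regular use imputed at 400 mcg/day, the generic supplement dose;
unknown status counts as non-use (conservative toward the null) and is
logged. Exposure enters the models as quartile codes whose cutpoints
are the 25th/50th/75th percentiles of the **control** distribution
within each sex-by-study stratum; all subjects in the stratum are then
coded 1-4. Categorical quartiles limit the influence of the long right
tail of intake distributions and of between-study instrument
differences.

Choices the literature leaves open, fixed here:

* **Percentile definition.** Linear interpolation between order
  statistics (`quantile` type 7). Cutpoints -- hence codes -- depend on
  this, so it is pinned and tested.
* **Interval closure.** Code 1 is `value <= c25`; above that intervals
  are lower-open/upper-closed, so ties at a cutpoint take the lower
  code. Deterministic and order-preserving.
* **Case coding.** Cases are coded with the control cutpoints of their
  own sex-by-study stratum, not pooled cutpoints.
* **Trend coding.** Codes are carried as 1-4 and shifted to 0-3 where
  they enter as a linear trend, which keeps the model intercept
  interpretable; score tests and the trend OR are invariant to the
  shift.
* **Missing data.** Complete-case on folate and energy, with dropped
  counts logged. A stratum must contribute at least 8 controls;
  all-identical control values collapse the stratum to code 1 with a
  warning.

# Genetically predicted expression

For gene *g* with weight vector *w* over its variant set, the raw
prediction for subject *i* is `GReX_i = sum_k w_k d_ik` with `d` the
effect-allele dosage in [0, 2]. Weight sets are aligned to the study
genotypes by chromosome and position: an exact ref/effect-allele match
is used as-is, swapped alleles flip the dosage to `2 - d`, anything
else is dropped; all three actions are logged per variant. Genes whose
weight metadata explain less than 1% of expression variation
(`pred_r2 < 0.01`, boundary inclusive at 0.01) are excluded before
testing. GReX is standardized to mean 0, SD 1 over all analysis
subjects -- cases and controls together -- because the follow-up ORs
are reported per SD and the standardization population changes their
scale. Zero-variance predictions flag the gene degenerate rather than
producing NaNs. Strand-ambiguous (A/T, C/G) variants are matched by
their stated alleles like any others; synthetic data are
strand-consistent, and real-data users should pre-filter if their
pipelines cannot guarantee this.

# The per-gene interaction test

Let `y` be case status, `X` the covariates (age, sex, study indicators,
energy quartile score, principal components), `e` the folate quartile
score, and `G` the gene's aligned dosage matrix. All models are pooled
individual-level logistic regressions with study fixed effects, not
per-study meta-analysis.

**Fixed component.** The null model contains `X`, `e` and the gene's
standardized GReX. With fitted probabilities `mu` and
`W = diag(mu(1-mu))`, the score for the single interaction column
`c = GReX * e` is `U = c'(y - mu)`, its null variance
`V = c'Pc` with the efficient-score projection
`P = W - WX(X'WX)^{-1}X'W`, and `p_fixed = P(chi2_1 > U^2/V)`. The
projection is evaluated through a Cholesky factor of `X'WX`; `P` is
never formed.

**Random component.** Residual variant-level interactions that the
single GReX x E direction misses are tested by a variance-component
score. The null model *additionally* contains the GReX x E term, so
the fixed signal is absorbed; with centered columns `C_j = G_j * e`,
`Q = (y - mu)' C C' (y - mu)` has null distribution
`sum_k lambda_k chi2_1`, the `lambda_k` being eigenvalues of `C'PC`.
Variant main effects are *not* individually adjusted: weight sets can
reach hundreds of variants and per-variant main effects would
destabilize the null fit; this is the usual burden-style parsimony and
is a documented divergence risk from implementations that adjust them.

**Weighted-chi-square tails.** `davies_pvalue()` inverts the
characteristic function (Gil-Pelaez/Imhof form). The integrand
oscillates with a polynomially decaying envelope, which defeats a
single adaptive quadrature; the implementation integrates half-period
Gauss-Legendre panels and accelerates the alternating partial sums by
iterated averaging, with three guarded exits: an exact scaled
chi-square branch for (numerically) equal weights, a Lugannani-Rice
saddlepoint for the far tail where the inversion's absolute error
would swamp the value, and a Liu-type moment-matching fallback
(flagged in the output) if both fail. Central-range absolute accuracy
is ~1e-9 against a nested-quadrature oracle. All p-values are floored
at 1e-300.

**Adaptive combination.** For each weight `lambda` in
{0, 0.25, 0.5, 0.75, 1}, the statistic
`T(lambda) = -2[lambda log p_fixed + (1-lambda) log p_random]` has the
null law `lambda chi2_2 + (1-lambda) chi2_2`, a sum of two scaled
exponentials with a closed-form tail; endpoints reduce to the
components and `lambda = 0.5` is Fisher's method. The five per-weight
p-values are merged by the Cauchy (ACAT) combination. Because the grid
values are strongly dependent, the raw Cauchy value is mildly
non-uniform under the null (deviations ~0.005 in CDF, visible at 1e5
draws), so it is treated as a combining *statistic* and referred to
its exact null distribution under independent uniform components,
tabulated once per grid with a deterministic two-dimensional Fibonacci
lattice rule (~1.3M nodes, error ~1e-5) and cached. Single-element
grids skip the calibration, so `grid = {1}` returns `p_fixed` exactly
and `grid = {0.5}` is exactly Fisher. Below 1e-4 the tabulation is
continued linearly through the origin; the Cauchy combination is
tail-exact up to a slowly varying factor, so ordering and magnitude
are preserved where genome-wide decisions happen.

When a component is undefined -- a degenerate GReX, or a
single-variant gene whose interaction column is absorbed by the fixed
term -- the combination falls back to the other component and the
result is flagged (`single_variant`, `degenerate`). Genes never drop
out silently.

**The cost of adaptivity.** Against a *pure* fixed alternative the
adaptive p-value cannot match the fixed component it does not know is
right: at endpoint power 0.5-0.7 the gap at alpha 0.05 is ~0.10 for
the Cauchy combination (and essentially the same for a calibrated
min-p), shrinking below 0.05 once endpoint power exceeds ~0.93. This
is an inherent price of protecting against both alternatives and is
why the power-ordering checks in the test suite use well-powered
effects.

# Null-model numerics

Logistic fits use iteratively reweighted least squares: at most 50
iterations, convergence when the relative deviance change falls below
1e-10, Cholesky solves of the weighted normal equations, warm starts
along the scan (covariate fit -> per-gene null -> null + interaction).
Aliased columns are dropped with a message; fitted probabilities
within 1e-10 of 0/1 (separation) and one-class outcomes are errors,
not warnings. The fit matches `stats::glm` to ~1e-8, which the test
suite asserts as a cross-check.

# Follow-up models

Follow-ups use Wald inference (score tests are reserved for the scan):

* `exposure_trend_or()`: OR of disease per quartile increase in
  folate, covariate-adjusted, with optional extra covariates for
  sensitivity analyses.
* `stratified_expression_or()`: one model with quartile indicators,
  GReX, and GReX x quartile terms; the OR per SD of predicted
  expression within quartile q is `exp(beta_grex + beta_int_q)` with
  delta-method CIs, and each `beta_int_q` tests that quartile against
  the lowest. A single model with interaction terms (not subset
  refits) yields the "difference vs lowest quartile" p-values
  directly.
* `variant_driver_scan()`: after greedy position-order LD pruning at
  squared correlation 0.9 (first variant in position order survives a
  correlated pair; monomorphic variants are uninformative and
  removed), one model per retained variant with all retained variants'
  main effects and that variant's interaction; the exponentiated
  interaction coefficient is a ratio of odds ratios per quartile
  increase. The per-variant models do not adjust for the GReX main
  effect by default (configurable by adding it to the covariates).
* `single_variant_interaction()`: the same model for one pre-specified
  variant per additional effect allele.

Genes flagged at FDR q = 0.2 are routed by comparing component
p-values: `p_fixed <= p_random` sends a gene to the stratified-OR
follow-up, otherwise to the driver scan. The routing rule is a
package decision (the narrative description it operationalizes does
not give a formula) and is configurable.

# The synthetic cohort generator

No consortium microdata are distributable, so every downstream stage
is exercised on generated cohorts with stored ground truth
(`sim_truth`): realized prediction R2 per gene, all generating
coefficients, drawn variant-level effects, the population disease
prevalence and the population quartile cutpoints.

What it emulates, and how the defaults were chosen:

* **Genotypes**: biallelic dosages from thresholding a latent AR(1)
  Gaussian per LD block, giving exact Hardy-Weinberg marginals at the
  drawn MAF and within-block correlation decaying as `rho^|i-j|` on
  the latent scale -- simple, reproducible LD with a closed-form
  orthant-probability oracle for tests.
* **Weights**: sparse normal weight vectors on a subset of block
  variants; the latent expression trait is `Gw + noise` with the noise
  variance set from the target R2, and the *realized* in-sample R2 is
  what the weight metadata carry, mirroring how PredictDB files carry
  training R2.
* **Exposure**: dietary folate log-normal (median 300 mcg/day, log-SD
  0.5 by default -- the source literature reports only quartiles, so
  the shape is a documented stand-in with parameters in the config);
  a supplement-user mixture (30% users at 400 mcg/day); total energy
  log-normal around 1900 kcal/day; age truncated normal (62 +/- 9,
  bounded to 18-90); balanced sexes; uniform study assignment;
  standard-normal PC covariates. Ages and energy are generated
  independently of genotype -- confounding scenarios are a config
  extension, not a default.
* **Outcome**: a logistic model on the population with main effects
  plus `gamma_fixed * GReX * q` and dispersed `b_j ~ N(0,
  tau_random^2)` variant-level interactions (deterministic per-variant
  coefficients can be supplied via `b_fixed`, e.g. to construct a
  purely random-component signal orthogonal to the expression
  weights), then case-control
  subsampling without replacement (`simulate-population-then-
  subsample`, one code path for cohort-style and case-control
  designs). The generating exposure code uses *population* DFE
  quartiles while the analysis re-derives control-based sex-by-study
  quartiles -- a deliberate, realistic mismatch recorded in the truth
  object.
* **Population prevalence**: the default intercept puts the population
  case fraction near 0.25-0.30. Real colorectal-cancer risk is far
  lower, but the logistic interaction analysis conditions on
  case-control sampling, making the intercept a nuisance parameter;
  a higher prevalence keeps the simulated populations (which must be
  several times the sampled case count) at tractable sizes. This is a
  simulation-design choice, documented here once.

What it does **not** emulate: genotyping or imputation error, missing
FFQ items, population stratification beyond the supplied PC columns,
linkage across blocks, fortification-era recalculations of
study-specific FFQ values (assumed applied upstream of the phenotype
file). Passing tests therefore demonstrate correctness of the
statistics under the stated model, not robustness to those artifacts.

# Problem sizes in the test suite

The acceptance-style checks run at the sizes that make their
guarantees meaningful: null calibration pools 2000 gene-tests at
2000+2000 subjects; the power-ranking check injects one
`gamma_fixed = 0.3` gene among 200 and repeats 50 times at 4000+4000;
follow-up coverage uses 200 replicates. Module-level tests re-assert
the same properties at smaller sizes so each file stays fast. All
simulations are seeded; the suite is deterministic.

A marginalization effect worth knowing when reading demo output:
injected interaction terms add variance to the linear predictor that
grows with the exposure code, and marginalizing a logistic model over
that extra dispersion pulls the *marginal* exposure trend toward the
null (logistic non-collapsibility). A generating trend of OR 0.91 per
quartile is therefore recovered slightly attenuated whenever strong
interactions are simulated alongside it; with interactions absent the
trend is recovered unbiasedly, which is what the recovery tests check.

# Known limitations

* The adaptive combination's null calibration assumes the two
  components are independent; empirically their normal-score
  correlation is ~0.02 under the null here, and the calibration holds,
  but strong LD-by-exposure structure in real data could induce
  dependence the tabulation does not model.
* The far-tail (~< 1e-8) weighted-chi-square probabilities come from a
  saddlepoint approximation with small relative error; ordering is
  reliable, absolute values at 1e-40 are approximations.
* Wald CIs in follow-ups are first-order; with sparse cells (an empty
  quartile, a near-monomorphic variant) coefficients are flagged or
  dropped rather than regularized.
* The analysis assumes weight sets and genotypes share a genome build
  and strand convention; alignment drops mismatches rather than
  attempting liftover or strand inference.
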
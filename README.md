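# folategxe

Set-based gene–environment interaction scans of genetically predicted
gene expression against dietary folate intake, for pooled case–control
studies of colorectal cancer.

## The problem

Higher folate intake is associated with lower colorectal cancer risk,
and folate metabolism feeds DNA synthesis, methylation and repair —
pathways where common genetic variation could plausibly modify the
association. Variant-by-variant interaction tests are underpowered, so
this package tests each *gene* as a set: the variants that predict the
gene's expression in colon tissue (PrediXcan-style weight sets) are
aggregated into genetically predicted expression (GReX), and the
gene-level question becomes "does predicted expression modify the
folate association?".

## The statistic

For gene *g*, let `d_ik` be effect-allele dosages, `w_k` the expression
weights, `GReX_i = Σ_k w_k d_ik` (standardized over analysis subjects),
and `e_i` the sex-by-study, control-based folate quartile score. With a
covariate-adjusted logistic null model (age, sex, study, energy
quartiles, principal components; fitted probabilities `μ`, weights
`W = diag(μ(1−μ))`, projection `P = W − WX(X'WX)⁻¹X'W`), the test has
two score components:

* **fixed** — 1 df, burden-style, for the column `c = GReX·e`:
  `U = c'(y−μ)`, `V = c'Pc`, `p_fixed = P(χ²₁ > U²/V)`;
* **random** — a variance component for residual variant-level
  interactions left after absorbing the fixed term: with centered
  columns `C_j = G_j·e`, `Q = (y−μ)'CC'(y−μ)` follows
  `Σ_k λ_k χ²₁` under the null, `λ_k` the eigenvalues of `C'PC`,
  evaluated by characteristic-function inversion with a saddlepoint
  far-tail and a Liu-type fallback;
* **adaptive** — `T(λ) = −2[λ log p_fixed + (1−λ) log p_random]` over
  the weight grid {0, 0.25, 0.5, 0.75, 1} (endpoints are the
  components; λ = 0.5 is Fisher's method), merged by a Cauchy
  combination that is referred to its exact null distribution.

Genome-scan control uses Bonferroni (0.05/m) and Benjamini–Hochberg at
q = 0.2; flagged genes are routed to follow-up GLMs — quartile-
stratified ORs per SD of expression when the fixed component drives
the signal, an LD-pruned (r² < 0.9) variant-level driver scan when the
random component does.

Because consortium microdata are not distributable, the package ships
a synthetic cohort generator (LD-blocked genotypes in Hardy–Weinberg
equilibrium, sparse weight sets with known prediction R², a
supplement-user folate mixture, and a logistic disease model with
known interaction effects) so every stage runs against stored ground
truth. See `vignettes/interaction-scan-methods.Rmd` for the full
methods account.

## Worked example

The `analysis/` scripts run the whole workflow on a generated
case–control study (2 studies, 2000 cases + 2000 controls, 20 genes;
gene `FIX01` carries a fixed GReX×folate interaction of 0.25 per SD
per quartile, `RAN01` carries dispersed variant-level interactions,
and folate itself is protective at OR 0.91 per quartile):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_harmonize.R
Rscript analysis/03_predict_expression.R
Rscript analysis/04_scan.R
Rscript analysis/05_followup.R
Rscript analysis/06_operating_characteristics.R
```

Stage 4 prints the scan (all tables are also written under
`results/`):

```
20 genes tested; Bonferroni threshold 2.50e-03
FDR (q = 0.2) flags 4 gene(s)

Top genes:
 gene_id     r2 n_snps_used  p_fixed p_random p_adaptive
   FIX01 0.0437           4 1.54e-15  0.44854   4.21e-15
  NULL07 0.0497           4 1.78e-04  0.14606   3.19e-04
   RAN01 0.0886           4 4.05e-02  0.00274   2.46e-03
```

`FIX01` is detected through its fixed component and `RAN01` through
its random component, exactly matching how they were generated (with
q = 0.2 the FDR flag list deliberately admits some false positives —
here two null genes ride along). Stage 5 then routes them:

```
Folate trend: OR 0.948 (95% CI 0.898, 1.002) per quartile

FIX01: fixed-effects driven -> stratified ORs per SD GReX
 quartile   or ci_low ci_high    p_int
        1 1.02  0.901    1.16       NA
        2 1.30  1.138    1.47 9.87e-03
        3 1.63  1.422    1.87 7.74e-07
        4 2.11  1.821    2.43 1.44e-13

RAN01: random-effects driven -> variant driver scan
   4 variants, 4 after r2 < 0.9 pruning
    variant_id ratio_or     se ci_low ci_high  p_int
 2:2010000_A/C    0.975 0.0426  0.897    1.06 0.5542
 2:2015000_C/A    1.086 0.0425  0.999    1.18 0.0526
 ...
```

The stratified ORs rise monotonically across folate quartiles — the
signature of a positive expression-by-folate interaction — and the
driver scan reports per-variant ratios of odds ratios per quartile
increase. The marginal folate trend (generated at OR 0.91) is
estimated at 0.948: the injected interactions disperse the linear
predictor and attenuate the marginal trend toward the null, a
non-collapsibility effect the methods vignette discusses.

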
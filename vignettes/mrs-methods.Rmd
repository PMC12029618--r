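---
title: "Methods: building and validating a metabolite risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a metabolite risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscore)
```

## The problem and the design

Dyslipidemia — elevated TG, LDL-C and total cholesterol with reduced
HDL-C — alters the plasma metabolome broadly, and single-metabolite
biomarkers replicate poorly across cohorts. A *metabolite risk score*
(MRS) pools several key metabolites into one number,

$$\mathrm{MRS} = \sum_i \beta_i M_i,$$

with $M_i \in \{0,1\}$ a binarized intensity call per key metabolite and
$\beta_i$ a standardized regression weight. The package implements the
two-phase workflow around this score: every selection and fitting step
runs on a *discovery* cohort; the finished score is *locked* and then
judged on an independent *replication* cohort. `run_pipeline()` executes
the whole funnel; each stage is also exported on its own.

## Stage by stage

### Multivariate screen: OPLS-DA

`fit_opls_da()` is a NIPALS orthogonal-PLS for a binary response: it
iteratively extracts components of X-variation uncorrelated with the
class label (orthogonal components), then a single predictive component —
one is all a binary y supports. Columns are mean-centered and
unit-variance scaled by default (`scaling = "uv"`, the common default in
commercial OPLS software; `pareto` and `none` are available). Constant
columns cannot be UV-scaled and are dropped with a warning.

Tunables:

* `n_orthogonal` (default 1): extraction stops early when an orthogonal
  component explains less than `min_var_explained` (default 1%) of the X
  sum of squares.
* `k_folds` (default 7) for `cross_validate_q2()`: folds are assigned
  round-robin in sample order, which keeps fold membership deterministic;
  folds that would lose a class are re-stratified within class. A seeded
  shuffle is available (`shuffle_seed`).
* `permutation_test()` defaults to 200 permutations; 20 is the floor
  below which the empirical p-value (floor $1/(n+1)$) is too coarse.

$R^2Y$ is the fraction of label variance explained in-fit; $Q^2Y = 1 -
\mathrm{PRESS}/\mathrm{SS}$ accumulates prediction error over held-out
folds with the model refit per fold, so $Q^2Y \le R^2Y$ and pure-noise
predictors give $Q^2Y \le 0$ in the typical case.

**CV-ANOVA.** `cv_anova()` tests the model by comparing PRESS to the
total label variation with an F statistic. Degrees-of-freedom conventions
for CV-ANOVA differ across the literature; we count only the predictive
component in the numerator (df1 = 1 for binary y) and charge the
orthogonal components to the residual df (df2 = n − 2 − n_orthogonal).
This is the most liberal of the documented variants, chosen deliberately:
cross-validation already penalizes overfitting, and fitting orthogonal
components to noise inflates PRESS, so the combined test errs
conservative. At the scale the tests use (197 metabolites, 50 samples per
group, 300 null simulations) the measured type-I error at $\alpha=0.05$
is nominal-to-conservative for the predictive-only model and strictly
conservative once an orthogonal component is added; the test suite
asserts both, and asserts that the median null $Q^2Y$ stays below zero.

**VIP.** With one predictive component, variable importance in projection
reduces to $\mathrm{VIP}_j = \sqrt{p}\,|w_j|/\lVert w\rVert$, normalized
so $\overline{\mathrm{VIP}^2} = 1$. OPLS VIP variants that fold in
orthogonal components exist; biomarker screening conventionally uses the
predictive-only form, which is what `vip_scores()` returns.

### Univariate screen and the major-metabolite filter

`univariate_screen()` runs Welch t-tests per metabolite on log
intensities (log2 by default, so fold changes read as log2-FC) and
adjusts with Benjamini–Hochberg q-values. The study this design follows
used an empirical-null density-estimation FDR; those q-values depend on
fitting heuristics that cannot be reproduced without the original data,
so the deterministic, assumption-light BH is the default and a Storey
$\pi_0$-rescaled variant is available (`fdr_method = "storey"`).

`select_major()` intersects the two screens: VIP ≥ 1.5 AND q < 0.05,
with VIPs from the per-mode OPLS models pooled after ranking (the two
ionization modes are modeled separately; survivors are unioned).

### Key metabolites: stepwise selection and ROC filter

`stepwise_select()` reproduces SPSS-style stepwise OLS of the 0/1 label
on the candidates — a linear probability model, deliberately not
logistic, matching how such screens are run in practice. Entry requires
the smallest partial-F p below `p_enter` (0.05); any included variable
whose p rises above `p_remove` (0.10) is removed; the loop is guarded
against entry/removal cycles. Candidates whose tolerance ($1 - R^2$
against the included set) falls below the threshold are *permanently
excluded and reported*: the default `"tolerance"` rule (tolerance <
1e-4) mimics SPSS, which only rejects near-perfect collinearity; the
stricter `"vif"` rule (VIF > 10, i.e. tolerance < 0.1) catches the
strong-but-imperfect collinearity (r ≈ 0.97) that the synthetic scenario
plants, and is what the acceptance script uses.

`roc_filter()` keeps survivors whose AUC differs from 0.5 at
`alpha = 0.05`, two-sided, using the exact midrank Mann–Whitney AUC and
the DeLong variance. AUCs are oriented so disease-elevated metabolites
score above 0.5.

### Scoring and lock-down

For each key metabolite `youden_cutoff()` scans the midpoints between
consecutive distinct sorted intensities (± infinite sentinels) and
returns the threshold maximizing $J = \mathrm{sens} + \mathrm{spec} - 1$;
ties break toward higher sensitivity, then the lower cut-off. Equality
with the exhaustive search over all thresholds is asserted in the tests.
An intensity exactly at the cut-off scores 0 ("strictly above" rule).
Constant intensities leave $J = 0$ everywhere; the +Inf sentinel is
returned with a warning rather than an arbitrary interior threshold.

`fit_betas()` enters all keys simultaneously and standardizes
coefficients by $\beta = b\,\mathrm{sd}(x)/\mathrm{sd}(y)$. Whether the
weights should be estimated on continuous intensities or on the 0/1
simple scores is genuinely ambiguous in this design's usual description;
both are implemented (`beta_predictors = "continuous"` (default) or
`"simple"`). In the continuous case each predictor is sign-oriented along
its scoring direction first, so that a disease-decreased key contributes
a positive weight to its below-cut-off call rather than a contradictory
sign pair.

Scoring direction defaults to "above → 1" in `build_mrs_model()` — the
convention when all keys are disease-elevated. The pipeline instead
orients each key by its ROC AUC (`direction_by_auc = TRUE`): synthetic
cohorts routinely promote disease-*decreased* metabolites to keys, and a
fixed "above" rule gives those a degenerate infinite cut-off.

`lock_model()` freezes keys, cut-offs, directions, weights and the
training MRS median into an immutable object (field assignment errors);
`write_mrs_model()` serializes it to JSON at full double precision, since
published cut-offs carry 13+ significant digits and truncation would
change calls near the threshold.

### Validation and re-grouping

`fit_model_suite()` builds the comparison suite — each key alone, the
lipid profile (TG, HDL-C, LDL-C, TC), the MRS, and MRS + lipid profile.
Multi-predictor models need a scalar score for ROC analysis; how the
original design collapsed them is unstated, so the suite fits a logistic
regression on the discovery cohort and locks the coefficients (an OLS
linear-probability combiner is the alternative flag). `roc_report()`
returns AUC (exact Mann–Whitney), DeLong SE, Wald 95% CI, p against 0.5,
and accuracy at the score's own Youden threshold — published "accuracy"
percentages in this design read as AUC × 100, so both are reported.

`regroup_by_mrs()` re-assigns replication samples by the locked
discovery-set MRS median: below the median → healthy, at or above →
dyslipidemia. Percentages are reported per *re-assigned* group (the
fraction of the MRS-healthy group that is truly healthy, etc.), which is
the arithmetic the published confusion counts follow; the cross-tab
itself is returned so per-true-group rates can be recomputed. Whether the
median should come from discovery or from the replication cohort itself
is ambiguous in the source design; the locked discovery median is the
default (`regroup_median = "discovery"`), since anything else leaks
replication information into a "locked" rule. `regrouped_opls()` then
refits OPLS-DA per mode against the re-grouped labels as a final
discrimination check.

## The synthetic cohort generator

`simulate_cohort()` draws log-normal intensities — Gaussian on the log
scale (mean 16.5, SD 0.6, putting median intensities near 1.5 × 10⁷
instrument units so Youden cut-offs have realistic magnitudes) — for
2 groups × 2 sets × `n_per_group_per_set` (default 50) samples and
128 + 69 metabolites across the two ionization modes. Planted
differential metabolites shift the dyslipidemia group by a configured
effect in SD units on the log scale; collinear pairs share a latent
factor plus independent noise, reaching their target correlation;
clinical covariates shift by the group deltas of the source study's
clinical table (age +7.6 y, body weight +7.1 kg, BMI +3.3 kg/m²,
glucose +29.3 mg/dL, modest lipid shifts), with SDs reconstructed from
the reported standard errors at n = 50. A t(5) heavy-tail option exists
for the log intensities.

`make_paper_like_scenario()` fixes the canonical test fixture: 12
differential metabolites — two disease-elevated keys (one per mode) at
2 SD carrying the largest effects, a disease-decreased collinear pair at
r = 0.97 (effect −1.2 SD each), and nine moderate effects around ±0.8 to
1 SD. The intent is a cohort on which the full funnel has a known right
answer: the two planted keys should be selected and one collinear twin
excluded.

What the generator does **not** emulate: chromatographic drift, batch and
injection-order effects, missing values and limit-of-detection censoring,
QC-sample structure, non-Gaussian log-intensity shapes beyond the t
option, and correlated metabolite *modules* (beyond the explicit pairs).
Passing tests on this generator therefore demonstrate the statistical
machinery, not robustness to real acquisition artifacts. The planted
effects are also strong by design, so absolute AUCs on the fixture run
higher than typical real-cohort values.

## Numerical choices and degenerate inputs

* Group coding is healthy = 0, dyslipidemia = 1 everywhere; positive
  weights and loadings mean disease-elevated.
* Missing intensities are rejected at construction; intensity tables are
  validated for shape, uniqueness, and non-negativity (raw scale only —
  log tables carry a transform record).
* Log transform requires a positive pseudocount when zeros are present;
  zero with pseudocount 0 is an error, not a silent -Inf.
* Zero-variance metabolites: p = 1 with a warning in the univariate
  screen; dropped with a warning under UV scaling in OPLS-DA.
* `cv_anova()` returns p = 1 (not an error) when PRESS ≥ SS.
* Stepwise selection errors after 2 × (candidates) + 2 steps as a cycle
  guard.
* The pipeline validates every threshold range up front and aborts with
  the failing stage's name on any stage error.

## Problem sizes used by the test suite

Simulation-backed checks run at deliberately chosen scales: 300 null
cohorts for CV-ANOVA calibration and null-Q²Y location; 50 pipeline seeds
for key-metabolite recovery and collinear-twin exclusion; 50 random
fixtures each for the Youden-vs-exhaustive and stepwise-vs-best-subset
oracles; 100 random fixtures for AUC = U/(n₁n₂); 200 seeds for the ROC
filter's null keep-rate; 100 cohorts for the t-test false-positive rate.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands.

## Known limitations

* The linear-probability stepwise and the OLS β weights inherit the
  known quirks of regressing a binary outcome by least squares; they are
  kept because they mirror the workflow this package models, not because
  they are optimal.
* BH q-values will not numerically match empirical-null FDR tools on the
  same data.
* One predictive component limits the model to binary phenotypes;
  multi-class OPLS-DA is out of scope.
* With `direction_by_auc = FALSE` and a disease-decreased key, the locked
  model cannot be built (degenerate cut-off) — by design, since the fixed
  rule is only coherent for elevated keys.
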
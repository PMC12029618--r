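# mrscore

Construction and validation of **metabolite risk scores (MRS)** from
case/control untargeted-metabolomics feature tables, built around the
two-phase (discovery/replication) design used in plasma dyslipidemia
biomarker studies.

A single disease rarely has a single metabolite biomarker. An MRS
aggregates several *key metabolites* into one weighted score,

```
MRS = Σᵢ βᵢ · Mᵢ
```

where `Mᵢ ∈ {0, 1}` is the *simple score* of key metabolite *i* — 1 when
its relative peak intensity lies strictly above its Youden-index cut-off —
and `βᵢ` is the standardized coefficient of an enter-method linear
regression of the 0/1 group label on the key metabolites. The score is
built and *locked* on a discovery cohort, then applied unchanged to an
independent replication cohort.

The package implements the full selection funnel in front of the score:

1. **OPLS-DA per ionization mode** (NIPALS, unit-variance scaling, one
   predictive + configurable orthogonal components) with cross-validated
   Q²Y, CV-ANOVA significance, label-permutation diagnostics and **VIP**
   scores — `fit_opls_da()`, `cross_validate_q2()`, `cv_anova()`,
   `permutation_test()`, `vip_scores()`.
2. **Univariate screen**: Welch t-tests on log intensities with FDR
   q-values — `univariate_screen()`.
3. **Major metabolites**: VIP ≥ 1.5 AND q < 0.05 — `select_major()`.
4. **Key metabolites**: SPSS-style stepwise linear regression with
   multicollinearity exclusion, then a per-metabolite ROC significance
   filter (DeLong) — `stepwise_select()`, `roc_filter()`.
5. **Scoring**: Youden cut-offs, standardized β weights, locked JSON
   model — `youden_cutoff()`, `fit_betas()`, `build_mrs_model()`,
   `compute_mrs()`.
6. **Validation**: ROC/accuracy comparison of the MRS against each key
   metabolite, the lipid profile (TG, HDL-C, LDL-C, TC) and the combined
   model, plus the MRS-median re-grouping analysis —
   `fit_model_suite()`, `evaluate_models()`, `regroup_by_mrs()`,
   `regrouped_opls()`.

Because real cohorts of this kind are not publicly deposited, the package
ships a synthetic cohort generator (`simulate_cohort()`,
`make_paper_like_scenario()`) that emulates the study structure: two
groups × two sets × 50 samples, 128 positive-mode + 69 negative-mode
log-normal metabolites, planted differential metabolites, a highly
collinear pair, and clinical covariates with realistic group shifts.

## Worked example

```r
library(mrscore)

res <- run_pipeline(run_config(seed = 1, collinearity_rule = "vif"))

res$screen$keys
#> [1] "N010" "P002" "P010" "P005" "P006" "P004" "P007" "N001"
res$screen$excluded$id        # collinear twin removed during stepwise entry
#> [1] "P001"

print(res$mrs_model)
#> <mrs_model> locked scoring rule MRS = sum(beta_i * M_i)
#>   N010: beta = 0.3216, cut-off = 33802800.2008407 (above -> 1)
#>   P002: beta = 0.1922, cut-off = 11472546.0388385 (below -> 1)
#>   ...
#>   training MRS median = 0.785293

ev <- res$evaluation$replication
ev[ev$model %in% c("lipid_profile", "mrs", "mrs_lipid"), ]
#>            model   auc ci_lower ci_upper         p accuracy
#>    lipid_profile 0.787    0.699    0.874  1.37e-10     0.74
#>              mrs 0.977    0.955    1.000   < 1e-300     0.93
#>        mrs_lipid 0.970    0.940    0.999 4.26e-214     0.93

print(res$regroup)
#> <regroup_summary> threshold = 0.785293
#>               true
#> mrs_group      healthy dyslipidemia
#>   healthy           48            7
#>   dyslipidemia       2           43
#>   correctly identified: healthy 87.3%, dyslipidemia 95.6%
```

Reading the output: the screen found the planted differential metabolites,
excluded one member of the collinear pair, and locked an 8-key MRS on the
discovery half. Applied unchanged to the replication half, the MRS
discriminates the groups (AUC 0.977) better than the lipid profile alone
(0.787), and the median split re-assigns samples so that 87.3% of the
MRS-healthy group and 95.6% of the MRS-dyslipidemia group carry the
matching true label. On synthetic cohorts with several strong planted
effects the MRS is stronger than in typical real data; the methods
vignette (`vignettes/mrs-methods.Rmd`) discusses what the simulation does
and does not emulate.

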
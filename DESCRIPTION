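Package: mrscore
Title: Metabolite Risk Score Construction and Validation for Case/Control Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates weighted metabolite risk scores (MRS) from
    untargeted case/control metabolomics feature tables. Implements OPLS-DA
    (orthogonal partial least squares discriminant analysis) with
    cross-validated Q2Y, CV-ANOVA significance testing, label-permutation
    diagnostics and VIP scores; univariate screening with FDR q-values;
    stepwise key-metabolite selection with multicollinearity exclusion;
    ROC-based key-metabolite filtering; Youden-index cut-off selection;
    construction of a locked binary risk score MRS = sum(beta_i * M_i) with
    standardized regression weights; independent-cohort validation; and
    median-split re-grouping analysis. Includes a synthetic cohort generator
    emulating two-phase (discovery/replication) dyslipidemia study designs,
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
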
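#' Fit the diagnostic model suite on a discovery cohort
#'
#' Builds the comparison set of diagnostic models: each key metabolite
#' alone, the lipid profile (TG, HDL-C, LDL-C, TC), the MRS alone, and
#' MRS + lipid profile. Multi-predictor models are collapsed to a single
#' per-sample score by logistic regression fitted on the discovery cohort;
#' the coefficients are locked so replication scoring never refits.
#'
#' @param features discovery [feature_table()] (raw intensities).
#' @param meta matching discovery [cohort_metadata()].
#' @param mrs_model a locked [lock_model()] scoring rule.
#' @param lipid_vars metadata columns holding the lipid profile (default
#'   `c("tg", "hdl_c", "ldl_c", "tc")`).
#' @param combiner `"logistic"` (default) or `"ols"` linear-probability
#'   combination for multi-predictor models.
#' @return A `model_suite` of locked scoring rules.
#' @export
fit_model_suite <- function(features, meta, mrs_model,
                            lipid_vars = c("tg", "hdl_c", "ldl_c", "tc"),
                            combiner = c("logistic", "ols")) {
  combiner <- match.arg(combiner)
  stopifnot(inherits(mrs_model, "mrs_model"))
  meta <- check_joint(features, meta)
  missing_lip <- setdiff(lipid_vars, names(meta))
  if (length(missing_lip)) {
    stop("missing lipid covariate(s): ", paste(missing_lip, collapse = ", "),
         call. = FALSE)
  }
  y <- group_code(meta)
  mrs <- compute_mrs(mrs_model, features)$mrs
  fit_combo <- function(Z) {
    d <- data.frame(y = y, Z, check.names = FALSE)
    if (combiner == "logistic") {
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = d, family = stats::binomial()))
    } else {
      fit <- stats::lm(y ~ ., data = d)
    }
    stats::coef(fit)
  }
  models <- list()
  for (k in mrs_model$keys) {
    models[[paste0("metabolite_", k)]] <-
      list(type = "single_metabolite", predictors = k)
  }
  models$lipid_profile <- list(type = "combined", predictors = lipid_vars,
                               coef = fit_combo(meta[, lipid_vars,
                                                     drop = FALSE]))
  models$mrs <- list(type = "mrs", predictors = "mrs")
  Zc <- cbind(mrs = mrs, meta[, lipid_vars, drop = FALSE])
  models$mrs_lipid <- list(type = "combined",
                           predictors = c("mrs", lipid_vars),
                           coef = fit_combo(Zc))
  structure(list(models = models, mrs_model = mrs_model,
                 lipid_vars = lipid_vars, combiner = combiner),
            class = "model_suite")
}

#' Score a cohort with a locked model suite
#'
#' @param suite a [fit_model_suite()] result.
#' @param features [feature_table()] of the cohort to score.
#' @param meta matching [cohort_metadata()] (for the lipid covariates).
#' @return A data frame of per-sample scores, one column per model plus
#'   `sample_id`.
#' @export
score_model_suite <- function(suite, features, meta) {
  stopifnot(inherits(suite, "model_suite"))
  meta <- check_joint(features, meta)
  mrs <- compute_mrs(suite$mrs_model, features)$mrs
  out <- data.frame(sample_id = features$sample_ids,
                    stringsAsFactors = FALSE)
  for (nm in names(suite$models)) {
    m <- suite$models[[nm]]
    out[[nm]] <- switch(
      m$type,
      single_metabolite = features$intensities[, m$predictors],
      mrs = mrs,
      combined = {
        Z <- if ("mrs" %in% m$predictors) {
          cbind(mrs = mrs,
                meta[, setdiff(m$predictors, "mrs"), drop = FALSE])
        } else {
          meta[, m$predictors, drop = FALSE]
        }
        drop(as.matrix(cbind(1, Z)) %*% m$coef)   # locked linear predictor
      }
    )
  }
  out
}

#' ROC diagnostic report for one scalar score
#'
#' AUC by the trapezoidal rule (equal to the Mann-Whitney statistic
#' U/(n1*n2)), DeLong standard error, Wald 95% confidence interval, a
#' two-sided p-value against AUC = 0.5, and the classification accuracy at
#' the Youden-optimal threshold of the score (oriented along the AUC).
#'
#' @param score per-sample scalar score.
#' @param y 0/1 group coding (or labels / metadata).
#' @return A one-row data frame: `auc`, `se`, `ci_lower`, `ci_upper`, `p`,
#'   `accuracy`, `n`.
#' @export
roc_report <- function(score, y) {
  if (is.data.frame(y) || is.character(y) || is.factor(y)) y <- group_code(y)
  stopifnot(length(score) == length(y), any(y == 0), any(y == 1))
  a <- auc_delong(score, y)
  ci <- pmin(pmax(a$auc + c(-1, 1) * stats::qnorm(0.975) * a$se, 0), 1)
  dirn <- if (a$auc >= 0.5) "above" else "below"
  cut <- suppressWarnings(youden_cutoff(score, y, direction = dirn))
  pred <- if (is.finite(cut)) simple_score(score, cut, dirn) else
    rep(0L, length(score))
  data.frame(auc = a$auc, se = a$se, ci_lower = ci[1], ci_upper = ci[2],
             p = a$p, accuracy = mean(pred == y), n = length(y))
}

#' Evaluate a locked model suite on a cohort
#'
#' @param suite a [fit_model_suite()] result.
#' @param features [feature_table()] of the cohort to evaluate.
#' @param meta matching [cohort_metadata()].
#' @return A data frame with one [roc_report()] row per model, plus `model`
#'   and `predictors` columns.
#' @export
evaluate_models <- function(suite, features, meta) {
  scores <- score_model_suite(suite, features, meta)
  meta <- check_joint(features, meta)
  y <- group_code(meta)
  rows <- lapply(names(suite$models), function(nm) {
    r <- roc_report(scores[[nm]], y)
    cbind(data.frame(model = nm,
                     predictors = paste(suite$models[[nm]]$predictors,
                                        collapse = "+"),
                     stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median-split re-grouping by MRS
#'
#' Samples with MRS below the locked training median are re-assigned to
#' the healthy group; samples at or above it go to the dyslipidemia group.
#' The cross-tabulation against the true groups is reported together with
#' the percent of each re-assigned group that carries the matching true
#' label (i.e. the fraction of the MRS-healthy group that is truly healthy,
#' and of the MRS-dyslipidemia group that is truly diseased).
#'
#' @param scores result of [compute_mrs()] (or a numeric MRS vector).
#' @param meta matching [cohort_metadata()].
#' @param threshold the locked training-set MRS median.
#' @return A `regroup_summary`: `threshold`, `counts` (re-assigned MRS
#'   group x true group), `n_regrouped` (re-assigned group sizes),
#'   `percent_correct` (per re-assigned group), `predicted` labels.
#' @export
regroup_by_mrs <- function(scores, meta, threshold) {
  mrs <- if (is.data.frame(scores)) scores$mrs else as.numeric(scores)
  stopifnot(is.finite(threshold))
  y <- group_code(meta)
  stopifnot(length(mrs) == length(y))
  pred <- ifelse(mrs < threshold, "healthy", "dyslipidemia")
  lev <- c("healthy", "dyslipidemia")
  counts <- table(factor(pred, lev),
                  factor(ifelse(y == 1, "dyslipidemia", "healthy"), lev))
  names(dimnames(counts)) <- c("mrs_group", "true")
  pct <- 100 * diag(counts) / rowSums(counts)
  structure(
    list(threshold = threshold, counts = unclass(counts),
         n_regrouped = rowSums(counts),
         percent_correct = pct, predicted = pred),
    class = "regroup_summary"
  )
}

#' @export
print.regroup_summary <- function(x, ...) {
  cat("<regroup_summary> threshold =", format(x$threshold, digits = 6), "\n")
  print(x$counts)
  cat(sprintf("  correctly identified: healthy %.1f%%, dyslipidemia %.1f%%\n",
              x$percent_correct["healthy"],
              x$percent_correct["dyslipidemia"]))
  invisible(x)
}

#' OPLS-DA on MRS-derived group labels
#'
#' Refits OPLS-DA per ionization mode against the re-grouped (MRS-derived)
#' labels, with cross-validated Q2Y, CV-ANOVA p-value and, optionally, a
#' label-permutation diagnostic.
#'
#' @param features [feature_table()] of the re-grouped cohort (raw or
#'   log-transformed).
#' @param labels re-grouped labels (from [regroup_by_mrs()]`$predicted`,
#'   or 0/1).
#' @param n_orthogonal,k_folds,scaling as in [fit_opls_da()].
#' @param n_permutations permutations for the diagnostic (0 skips it).
#' @param seed permutation seed.
#' @return A named list (`positive`, `negative`) of lists with `model`,
#'   `R2Y`, `Q2Y`, `p_cvanova` and (optionally) `permutation`.
#' @export
regrouped_opls <- function(features, labels, n_orthogonal = 1, k_folds = 7,
                           scaling = "uv", n_permutations = 0, seed = 1L) {
  stopifnot(inherits(features, "feature_table"))
  if (is.character(labels) || is.factor(labels)) {
    labels <- group_code(as.character(labels))
  }
  modes <- intersect(c("positive", "negative"), unique(features$mode))
  out <- lapply(modes, function(md) {
    ft <- subset_feature_table(features,
                               metabolites = which(features$mode == md))
    fit <- suppressWarnings(
      fit_opls_da(ft, labels, n_orthogonal = n_orthogonal,
                  scaling = scaling))
    ca <- cv_anova(ft, labels, n_orthogonal = n_orthogonal,
                   k_folds = k_folds, scaling = scaling)
    res <- list(model = fit, R2Y = fit$R2Y, Q2Y = ca$Q2Y, p_cvanova = ca$p)
    if (n_permutations > 0) {
      res$permutation <- permutation_test(ft, labels,
                                          n_orthogonal = n_orthogonal,
                                          k_folds = k_folds,
                                          n_permutations = n_permutations,
                                          seed = seed, scaling = scaling)
    }
    res
  })
  names(out) <- modes
  out
}
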
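#' Per-metabolite univariate screen (Welch t-tests with FDR q-values)
#'
#' Runs a Welch two-sample t-test per metabolite on log intensities
#' (dyslipidemia vs healthy), reports the log2 fold change (dyslipidemia
#' minus healthy), and FDR-adjusted q-values.
#'
#' @param table a log-transformed [feature_table()] (see [log_transform()]).
#' @param meta matching [cohort_metadata()].
#' @param fdr_method `"BH"` (Benjamini-Hochberg step-up, default) or
#'   `"storey"` (BH rescaled by the Storey pi0 estimate at lambda = 0.5).
#' @return A data frame `(metabolite, mode, log2_fc, t, df, p, q)`, one row
#'   per metabolite in table order.
#' @export
univariate_screen <- function(table, meta, fdr_method = c("BH", "storey")) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$transform)) {
    stop("univariate_screen expects a log-transformed table; ",
         "call log_transform() first", call. = FALSE)
  }
  meta <- check_joint(table, meta)
  y <- group_code(meta)
  if (sum(y == 0) < 2L || sum(y == 1) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  X <- table$intensities
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  v0 <- apply(X[y == 0, , drop = FALSE], 2, stats::var)
  v1 <- apply(X[y == 1, , drop = FALSE], 2, stats::var)
  se2 <- v0 / n0 + v1 / n1
  tstat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1)),
               n0 + n1 - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  if (any(se2 == 0)) {
    warning("zero-variance metabolite(s) in both groups, p set to 1: ",
            paste(table$metabolite_ids[se2 == 0], collapse = ", "))
  }
  q <- fdr_adjust(p, method = fdr_method)
  log2_fc <- (m1 - m0) * log2(table$transform$base)
  data.frame(metabolite = table$metabolite_ids, mode = table$mode,
             log2_fc = unname(log2_fc), t = unname(tstat), df = unname(df),
             p = unname(p), q = unname(q), stringsAsFactors = FALSE)
}

#' FDR q-values from raw p-values
#'
#' @param p numeric vector of p-values.
#' @param method `"BH"` (default) or `"storey"`: BH q-values rescaled by the
#'   conservative Storey null-proportion estimate
#'   pi0 = min(1, mean(p > 0.5) / 0.5).
#' @return q-values in `[0, 1]`, monotone non-decreasing in p.
#' @export
fdr_adjust <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Select major metabolites: VIP >= threshold AND q < threshold
#'
#' The multivariate and univariate screens are intersected: a metabolite is
#' "major" when its VIP score passes `vip_threshold` and its FDR q-value
#' passes `q_threshold`. VIPs from per-mode models are supplied as one
#' named vector (union over modes).
#'
#' @param univ result of [univariate_screen()].
#' @param vip named numeric vector of VIP scores covering every metabolite
#'   in `univ` (concatenate the per-mode [vip_scores()] outputs).
#' @param vip_threshold VIP cut-off (default 1.5).
#' @param q_threshold q-value cut-off (default 0.05).
#' @return Character vector of major metabolite IDs, in `univ` order.
#' @export
select_major <- function(univ, vip, vip_threshold = 1.5, q_threshold = 0.05) {
  if (is.null(names(vip))) {
    stop("vip must be a named vector", call. = FALSE)
  }
  v <- vip[univ$metabolite]
  if (anyNA(v)) {
    stop("VIP missing for metabolite(s): ",
         paste(univ$metabolite[is.na(v)], collapse = ", "), call. = FALSE)
  }
  univ$metabolite[v >= vip_threshold & univ$q < q_threshold]
}

r_squared_on <- function(x, Z) {
  if (is.null(Z) || ncol(Z) == 0L) return(0)
  fit <- stats::lm.fit(cbind(1, Z), x)
  1 - sum(fit$residuals^2) / sum((x - mean(x))^2)
}

coef_p_values <- function(X, y) {
  # t-test p-values of each slope in OLS of y on X (with intercept)
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  s <- summary(fit)$coefficients
  p <- s[-1, 4]
  names(p) <- colnames(X)
  p
}

#' Stepwise key-metabolite selection with multicollinearity exclusion
#'
#' SPSS-style stepwise ordinary least squares of the 0/1 group label on the
#' candidate metabolites (a linear probability model, deliberately not
#' logistic). At each step the candidate with the smallest partial-F
#' p-value enters if below `p_enter`; any included variable whose p-value
#' rises above `p_remove` is then removed. Candidates violating the
#' collinearity rule against the currently included set are permanently
#' excluded and reported with their tolerance.
#'
#' @param X samples x candidates numeric matrix (named columns), or a
#'   [feature_table()] restricted to the candidates.
#' @param y 0/1 group coding (or labels / metadata).
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @param collinearity_rule `"tolerance"` (exclude when tolerance
#'   1 - R^2 < 1e-4, i.e. VIF > 1e4; the lenient default) or `"vif"`
#'   (stricter: exclude when VIF > 10).
#' @return A list: `survivors` (IDs in entry order), `excluded` (data frame
#'   `id`, `reason`, `tolerance`), `steps`.
#' @export
stepwise_select <- function(X, y, p_enter = 0.05, p_remove = 0.10,
                            collinearity_rule = c("tolerance", "vif")) {
  collinearity_rule <- match.arg(collinearity_rule)
  tol_threshold <- if (collinearity_rule == "tolerance") 1e-4 else 0.1
  info <- resolve_xy(X, y)
  X <- info$X; y <- info$y
  ids <- colnames(X)
  if (ncol(X) < 1L) stop("no candidates supplied", call. = FALSE)
  if (nrow(X) <= ncol(X) + 2L) {
    stop("stepwise needs n > candidates + 2", call. = FALSE)
  }
  included <- character(0)
  excluded <- data.frame(id = character(), reason = character(),
                         tolerance = numeric(), stringsAsFactors = FALSE)
  max_steps <- 2L * ncol(X) + 2L
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) {
      stop("stepwise selection did not converge (cycling between entry ",
           "and removal)", call. = FALSE)
    }
    changed <- FALSE
    pool <- setdiff(ids, c(included, excluded$id))
    if (length(pool)) {
      Zinc <- if (length(included)) X[, included, drop = FALSE] else NULL
      tol <- vapply(pool, function(id) 1 - r_squared_on(X[, id], Zinc),
                    numeric(1))
      bad <- tol < tol_threshold
      if (any(bad)) {
        excluded <- rbind(excluded, data.frame(
          id = pool[bad], reason = "multicollinearity",
          tolerance = tol[bad], stringsAsFactors = FALSE))
        pool <- pool[!bad]
      }
      if (length(pool)) {
        pvals <- vapply(pool, function(id) {
          ps <- coef_p_values(X[, c(included, id), drop = FALSE], y)
          unname(ps[id])
        }, numeric(1))
        if (min(pvals) < p_enter) {
          included <- c(included, pool[which.min(pvals)])
          changed <- TRUE
        }
      }
    }
    while (length(included)) {
      ps <- coef_p_values(X[, included, drop = FALSE], y)
      if (max(ps) > p_remove) {
        included <- setdiff(included, names(ps)[which.max(ps)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  rownames(excluded) <- NULL
  list(survivors = included, excluded = excluded, steps = steps)
}

auc_delong <- function(x, y) {
  # AUC oriented so disease-elevated values give AUC > 0.5, with DeLong
  # variance and a two-sided Wald p against AUC = 0.5. The AUC itself is
  # the Mann-Whitney U statistic over n1*n2 via midranks (ties count 1/2),
  # which is exact; pROC supplies the DeLong variance.
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  u <- sum(rank(x)[y == 1]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  r <- pROC::roc(response = y, predictor = x, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  v <- suppressWarnings(pROC::var(r))     # DeLong; warns when AUC == 1
  se <- sqrt(max(v, 0))
  p <- if (se == 0) {
    if (abs(auc - 0.5) < .Machine$double.eps^0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(auc - 0.5) / se)
  }
  list(auc = auc, se = se, p = p)
}

#' ROC significance filter for key metabolites
#'
#' Per candidate, the AUC for discriminating dyslipidemia from healthy
#' (oriented so disease-elevated intensities give AUC > 0.5), its DeLong
#' standard error and a two-sided p-value against AUC = 0.5. Candidates
#' with p < `alpha` become key metabolites.
#'
#' @param X samples x candidates matrix (named columns) or
#'   [feature_table()] restricted to the stepwise survivors.
#' @param y 0/1 group coding (or labels / metadata).
#' @param alpha significance level (default 0.05).
#' @return A list: `stats` (data frame `metabolite`, `auc`, `se`, `p`,
#'   `kept`) and `keys` (IDs kept).
#' @export
roc_filter <- function(X, y, alpha = 0.05) {
  info <- resolve_xy(X, y)
  X <- info$X; y <- info$y
  if (ncol(X) < 1L) stop("no survivors supplied", call. = FALSE)
  rows <- lapply(colnames(X), function(id) {
    a <- auc_delong(X[, id], y)
    data.frame(metabolite = id, auc = a$auc, se = a$se, p = a$p,
               kept = a$p < alpha, stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, rows)
  rownames(stats_df) <- NULL
  list(stats = stats_df, keys = stats_df$metabolite[stats_df$kept])
}

#' Clinical covariate comparison between groups
#'
#' Per-variable group means with standard errors, an unadjusted p-value
#' (Welch t-test; variables listed in `log_vars` are tested after log
#' transformation) and a confounder-adjusted p-value (group coefficient of
#' an OLS of the variable on group plus the confounders). Categorical
#' variables (e.g. sex) are compared by a chi-squared test. Variables that
#' are themselves confounders get `NA` for the adjusted p-value, since a
#' variable cannot be adjusted by itself.
#'
#' @param meta a [cohort_metadata()] data frame.
#' @param adjust_for confounder column names (default
#'   `c("age", "weight", "bmi")`).
#' @param variables covariates to compare; default all columns except
#'   `sample_id`, `group`, `set`.
#' @param log_vars variables to log-transform before testing.
#' @return A data frame with one row per variable: group means, SEs, `p_unadjusted`,
#'   `p_adjusted`, and the test used.
#' @export
clinical_compare <- function(meta, adjust_for = c("age", "weight", "bmi"),
                             variables = NULL, log_vars = NULL) {
  stopifnot(inherits(meta, "cohort_metadata") || is.data.frame(meta))
  y <- group_code(meta)
  if (is.null(variables)) {
    variables <- setdiff(names(meta), c("sample_id", "group", "set"))
  }
  adjust_for <- intersect(adjust_for, names(meta))
  rows <- lapply(variables, function(v) {
    x <- meta[[v]]
    if (is.numeric(x)) {
      xt <- x
      if (v %in% log_vars) {
        if (any(x <= 0)) stop("log_vars variable '", v,
                              "' has non-positive values", call. = FALSE)
        xt <- log(x)
      }
      tt <- stats::t.test(xt[y == 1], xt[y == 0])
      p_adj <- if (v %in% adjust_for) NA_real_ else {
        adjusted_group_p(xt, y, meta, adjust_for)
      }
      data.frame(variable = v,
                 mean_healthy = mean(x[y == 0]),
                 se_healthy = stats::sd(x[y == 0]) / sqrt(sum(y == 0)),
                 mean_dyslipidemia = mean(x[y == 1]),
                 se_dyslipidemia = stats::sd(x[y == 1]) / sqrt(sum(y == 1)),
                 p_unadjusted = tt$p.value, p_adjusted = p_adj,
                 test = "welch_t", stringsAsFactors = FALSE)
    } else {
      ct <- stats::chisq.test(table(y, x), correct = FALSE)
      data.frame(variable = v, mean_healthy = NA_real_, se_healthy = NA_real_,
                 mean_dyslipidemia = NA_real_, se_dyslipidemia = NA_real_,
                 p_unadjusted = ct$p.value, p_adjusted = NA_real_,
                 test = "chi_squared", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

adjusted_group_p <- function(x, y, meta, adjust_for) {
  if (!length(adjust_for)) return(NA_real_)
  Z <- meta[, adjust_for, drop = FALSE]
  if (!all(vapply(Z, is.numeric, logical(1)))) {
    stop("confounders must be numeric", call. = FALSE)
  }
  df <- data.frame(x = x, group = y, Z, check.names = FALSE)
  fit <- stats::lm(x ~ ., data = df)
  summary(fit)$coefficients["group", 4]
}
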
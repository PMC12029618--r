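#' Fit OPLS-DA for a binary phenotype
#'
#' Orthogonal projections to latent structures discriminant analysis,
#' NIPALS style: variation in X uncorrelated with the class label is
#' stripped into orthogonal components, then a single predictive component
#' is extracted (one is all a binary response supports). Columns are
#' mean-centered and, by default, unit-variance scaled.
#'
#' @param X a [feature_table()] or a numeric samples x metabolites matrix.
#' @param y group labels: 0/1 coding, or `healthy`/`dyslipidemia` strings,
#'   or a [cohort_metadata()] data frame.
#' @param n_orthogonal number of orthogonal components to extract
#'   (default 1).
#' @param scaling column scaling: `"uv"` (unit variance, default),
#'   `"pareto"`, or `"none"`.
#' @param auto_stop stop extracting orthogonal components once one explains
#'   less than `min_var_explained` of the X variance (that component is
#'   discarded).
#' @param min_var_explained auto-stop threshold, fraction of X sum of
#'   squares (default 0.01).
#' @return An `opls_da` model: predictive scores `t`, loadings `p`, weights
#'   `w`, y-loading `c`, orthogonal `t_orth`/`p_orth`/`w_orth` matrices,
#'   `R2Y`, fitted values, and the centering/scaling parameters needed to
#'   project new samples.
#' @export
fit_opls_da <- function(X, y, n_orthogonal = 1, scaling = c("uv", "pareto", "none"),
                        auto_stop = TRUE, min_var_explained = 0.01) {
  scaling <- match.arg(scaling)
  info <- resolve_xy(X, y)
  X <- info$X; y <- info$y
  n <- nrow(X)
  if (length(unique(y)) < 2L) {
    stop("OPLS-DA requires both classes in y", call. = FALSE)
  }
  if (n <= n_orthogonal + 2L) {
    stop("too few samples for ", n_orthogonal, " orthogonal component(s)",
         call. = FALSE)
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  keep <- seq_len(ncol(X))
  if (scaling != "none" && any(sdev == 0)) {
    drop <- which(sdev == 0)
    warning("dropping ", length(drop), " constant metabolite column(s) under ",
            scaling, " scaling: ", paste(colnames(X)[drop], collapse = ", "))
    keep <- setdiff(keep, drop)
    X <- X[, keep, drop = FALSE]
    mu <- mu[keep]; sdev <- sdev[keep]
  }
  scale_fac <- switch(scaling, uv = sdev, pareto = sqrt(sdev),
                      none = rep(1, ncol(X)))
  scale_fac[scale_fac == 0] <- 1
  Xd <- sweep(sweep(X, 2, mu, "-"), 2, scale_fac, "/")
  ybar <- mean(y)
  yc <- y - ybar
  ss_x_tot <- sum(Xd^2)

  w_orth <- t_orth <- p_orth <- NULL
  n_orth_used <- 0L
  for (a in seq_len(n_orthogonal)) {
    w <- crossprod(Xd, yc)
    w <- w / sqrt(sum(w^2))
    tt <- Xd %*% w
    p <- crossprod(Xd, tt) / sum(tt^2)
    wo <- p - c(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break                       # X variation all predictive
    wo <- wo / nwo
    to <- Xd %*% wo
    po <- crossprod(Xd, to) / sum(to^2)
    frac <- sum(to^2) * sum(po^2) / ss_x_tot
    if (auto_stop && frac < min_var_explained) break
    Xd <- Xd - to %*% t(po)
    w_orth <- cbind(w_orth, wo)
    t_orth <- cbind(t_orth, to)
    p_orth <- cbind(p_orth, po)
    n_orth_used <- n_orth_used + 1L
  }

  w <- crossprod(Xd, yc)
  w <- w / sqrt(sum(w^2))
  tt <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, tt) / sum(tt^2))
  cc <- sum(yc * tt) / sum(tt^2)
  yhat <- tt * cc + ybar
  R2Y <- 1 - sum((y - yhat)^2) / sum(yc^2)

  structure(
    list(w = drop(w), t = tt, p = p, c = cc,
         w_orth = w_orth, t_orth = t_orth, p_orth = p_orth,
         n_orthogonal = n_orth_used, n_orthogonal_requested = n_orthogonal,
         R2Y = R2Y, fitted = yhat, y = y, y_mean = ybar,
         center = mu, scale = scale_fac, scaling = scaling, keep = keep,
         metabolite_ids = colnames(X), subclass = info$subclass[keep],
         ion_mode = info$mode[keep]),
    class = "opls_da"
  )
}

resolve_xy <- function(X, y) {
  subclass <- NULL; mode <- NULL
  if (inherits(X, "feature_table")) {
    subclass <- X$subclass; mode <- X$mode
    X <- X$intensities
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("M%03d", seq_len(ncol(X)))
  if (is.data.frame(y)) y <- group_code(y)
  if (is.character(y) || is.factor(y)) y <- group_code(as.character(y))
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (anyNA(y)) stop("y contains missing values", call. = FALSE)
  if (is.null(subclass)) subclass <- rep("other", ncol(X))
  if (is.null(mode)) mode <- rep("positive", ncol(X))
  list(X = X, y = y, subclass = subclass, mode = mode)
}

#' @export
print.opls_da <- function(x, ...) {
  cat("<opls_da> 1 predictive + ", x$n_orthogonal,
      " orthogonal component(s), ", length(x$w), " metabolites\n",
      "  R2Y = ", format(x$R2Y, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Project new samples through a fitted OPLS-DA model
#'
#' Applies the stored centering/scaling, removes the orthogonal components,
#' and returns the predictive score and predicted (continuous) class value.
#'
#' @param object a fitted `opls_da` model.
#' @param newdata a [feature_table()] or matrix with the model's metabolite
#'   columns.
#' @param ... unused.
#' @return A list with `score` (predictive score t) and `y_pred`.
#' @export
predict.opls_da <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$intensities
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$metabolite_ids)) {
    idx <- match(object$metabolite_ids, colnames(newdata))
    if (anyNA(idx)) stop("newdata is missing model metabolite columns",
                         call. = FALSE)
    newdata <- newdata[, idx, drop = FALSE]
  } else {
    newdata <- newdata[, object$keep, drop = FALSE]
  }
  Xd <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  for (a in seq_len(object$n_orthogonal)) {
    to <- Xd %*% object$w_orth[, a]
    Xd <- Xd - to %*% t(object$p_orth[, a])
  }
  score <- drop(Xd %*% object$w)
  list(score = score, y_pred = score * object$c + object$y_mean)
}

cv_folds <- function(y, k_folds, fold_scheme = c("round_robin", "stratified"),
                     shuffle_seed = NULL) {
  fold_scheme <- match.arg(fold_scheme)
  n <- length(y)
  ord <- seq_len(n)
  if (!is.null(shuffle_seed)) {
    ord <- withr::with_seed(shuffle_seed, sample.int(n))
  }
  fold <- integer(n)
  if (fold_scheme == "round_robin") {
    fold[ord] <- rep_len(seq_len(k_folds), n)
    bad <- vapply(seq_len(k_folds),
                  function(f) length(unique(y[fold != f])) < 2L, logical(1))
    if (any(bad)) fold_scheme <- "stratified"   # re-stratify degenerate folds
  }
  if (fold_scheme == "stratified") {
    for (cls in unique(y)) {
      idx <- ord[y[ord] == cls]
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  }
  fold
}

#' Cross-validated Q2Y of an OPLS-DA model
#'
#' K-fold cross-validation (deterministic round-robin fold assignment in
#' sample order by default; folds that would lose a class are re-stratified
#' within class). The model is refit on each training fold, held-out
#' samples are projected, and Q2Y = 1 - PRESS / SS_tot.
#'
#' @inheritParams fit_opls_da
#' @param k_folds number of folds (default 7).
#' @param fold_scheme `"round_robin"` (default) or `"stratified"`.
#' @param shuffle_seed optional seed for a random fold shuffle; `NULL`
#'   (default) keeps assignment deterministic.
#' @return A list with `Q2Y`, `PRESS`, `SS` and the per-sample fold vector.
#' @export
cross_validate_q2 <- function(X, y, n_orthogonal = 1, k_folds = 7,
                              scaling = "uv",
                              fold_scheme = "round_robin",
                              shuffle_seed = NULL) {
  info <- resolve_xy(X, y)
  X <- info$X; y <- info$y
  if (k_folds < 2L) stop("k_folds must be at least 2", call. = FALSE)
  fold <- cv_folds(y, k_folds, fold_scheme, shuffle_seed)
  press <- 0
  for (f in seq_len(k_folds)) {
    test <- fold == f
    if (!any(test)) next
    fit <- suppressWarnings(
      fit_opls_da(X[!test, , drop = FALSE], y[!test],
                  n_orthogonal = n_orthogonal, scaling = scaling)
    )
    pred <- predict(fit, X[test, , drop = FALSE])
    press <- press + sum((y[test] - pred$y_pred)^2)
  }
  ss <- sum((y - mean(y))^2)
  list(Q2Y = 1 - press / ss, PRESS = press, SS = ss, fold = fold)
}

#' CV-ANOVA significance test for an OPLS-DA model
#'
#' F-test comparing the cross-validated predictive residuals (PRESS) to the
#' total variation of the class label:
#' F = (SS - PRESS) / (PRESS / df_resid). The numerator degrees of freedom
#' count only the predictive component (one, for a binary response) — the
#' orthogonal components model variation unrelated to y and are not
#' predictive degrees of freedom, though they do consume residual df:
#' df_resid = n - 1 - 1 - n_orthogonal. CV-ANOVA df conventions vary across
#' the literature; this predictive-only choice is deliberate and is the
#' most liberal one, since fitting orthogonal components to noise already
#' makes the cross-validated test err conservative. When PRESS >= SS the
#' model carries no cross-validated evidence and p = 1 is returned.
#'
#' @inheritParams cross_validate_q2
#' @return A list with `p`, `F`, `df1`, `df2`, `Q2Y`, `PRESS`, `SS`.
#' @export
cv_anova <- function(X, y, n_orthogonal = 1, k_folds = 7, scaling = "uv",
                     fold_scheme = "round_robin", shuffle_seed = NULL) {
  cv <- cross_validate_q2(X, y, n_orthogonal = n_orthogonal,
                          k_folds = k_folds, scaling = scaling,
                          fold_scheme = fold_scheme,
                          shuffle_seed = shuffle_seed)
  n <- length(cv$fold)
  df1 <- 1
  df2 <- n - 2 - n_orthogonal
  if (df2 <= 0) stop("too few samples for CV-ANOVA", call. = FALSE)
  if (cv$PRESS >= cv$SS) {
    return(list(p = 1, F = 0, df1 = df1, df2 = df2, Q2Y = cv$Q2Y,
                PRESS = cv$PRESS, SS = cv$SS))
  }
  Fstat <- ((cv$SS - cv$PRESS) / df1) / (cv$PRESS / df2)
  list(p = stats::pf(Fstat, df1, df2, lower.tail = FALSE), F = Fstat,
       df1 = df1, df2 = df2, Q2Y = cv$Q2Y, PRESS = cv$PRESS, SS = cv$SS)
}

#' Label-permutation overfitting diagnostic for OPLS-DA
#'
#' Refits the model under random permutations of the class labels and
#' records permuted R2Y and Q2Y. The empirical p-value is
#' (1 + #\{Q2Y_perm >= Q2Y_obs\}) / (n_permutations + 1). Regression
#' intercepts of permuted R2Y and Q2Y against the absolute correlation
#' between permuted and true labels are reported as the usual
#' permutation-plot summary.
#'
#' @inheritParams cross_validate_q2
#' @param n_permutations number of label permutations (default 200;
#'   at least 20).
#' @param seed integer seed for the permutations.
#' @return A `permutation_report` list: observed and permuted R2Y/Q2Y,
#'   intercepts, and the empirical `p`.
#' @export
permutation_test <- function(X, y, n_orthogonal = 1, k_folds = 7,
                             n_permutations = 200, seed = 1L,
                             scaling = "uv") {
  if (n_permutations < 20L) {
    stop("n_permutations must be at least 20", call. = FALSE)
  }
  info <- resolve_xy(X, y)
  X <- info$X; y <- info$y
  obs_fit <- suppressWarnings(
    fit_opls_da(X, y, n_orthogonal = n_orthogonal, scaling = scaling))
  obs_cv <- cross_validate_q2(X, y, n_orthogonal = n_orthogonal,
                              k_folds = k_folds, scaling = scaling)
  perms <- withr::with_seed(seed, {
    replicate(n_permutations, sample(y), simplify = FALSE)
  })
  r2 <- q2 <- corr <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    yp <- perms[[i]]
    fit <- suppressWarnings(
      fit_opls_da(X, yp, n_orthogonal = n_orthogonal, scaling = scaling))
    cv <- cross_validate_q2(X, yp, n_orthogonal = n_orthogonal,
                            k_folds = k_folds, scaling = scaling,
                            fold_scheme = "stratified")
    r2[i] <- fit$R2Y
    q2[i] <- cv$Q2Y
    corr[i] <- abs(stats::cor(yp, y))
  }
  p_emp <- (1 + sum(q2 >= obs_cv$Q2Y)) / (n_permutations + 1)
  intercept <- function(v) {
    # intercept of v regressed on |cor(y_perm, y)| at correlation 0
    unname(stats::coef(stats::lm(v ~ corr))[1])
  }
  structure(
    list(n_permutations = n_permutations, R2Y_obs = obs_fit$R2Y,
         Q2Y_obs = obs_cv$Q2Y, R2Y_perm = r2, Q2Y_perm = q2,
         label_correlation = corr,
         R2Y_intercept = intercept(r2), Q2Y_intercept = intercept(q2),
         p = p_emp),
    class = "permutation_report"
  )
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("<permutation_report> ", x$n_permutations, " permutations\n",
      "  observed R2Y = ", format(x$R2Y_obs, digits = 4),
      ", Q2Y = ", format(x$Q2Y_obs, digits = 4), "\n",
      "  intercepts: R2Y ", format(x$R2Y_intercept, digits = 3),
      ", Q2Y ", format(x$Q2Y_intercept, digits = 3), "\n",
      "  empirical p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' VIP scores of a fitted OPLS-DA model
#'
#' Variable importance in projection computed from the predictive
#' component: VIP_j = sqrt(p * (w_j / ||w||)^2), with p the number of
#' metabolites, so mean(VIP^2) = 1. (With a single predictive component the
#' SSY weighting across components collapses; a variant including the
#' orthogonal components in the denominator exists but the predictive-only
#' form is what VIP-based biomarker screening uses.)
#'
#' @param model a fitted `opls_da` model.
#' @return A named non-negative numeric vector of VIP scores, one per
#'   metabolite retained in the model.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "opls_da"))
  w <- model$w / sqrt(sum(model$w^2))
  vip <- sqrt(length(w) * w^2)
  names(vip) <- model$metabolite_ids
  vip
}

#' Per-metabolite loading table grouped by subclass
#'
#' Restricts the model loadings to the `top_k` most frequent metabolite
#' subclasses (ignoring the catch-all `"other"`), the usual input for a
#' subclass-colored loading plot.
#'
#' @param model a fitted `opls_da` model.
#' @param subclass optional per-metabolite subclass annotations (named
#'   character vector or unnamed vector in model column order); defaults to
#'   the annotation carried by the feature table the model was fit on.
#' @param top_k number of subclasses to retain (default 3).
#' @return A data frame `(metabolite, subclass, predictive_loading,
#'   orthogonal_loading)`.
#' @export
loading_summary <- function(model, subclass = NULL, top_k = 3) {
  stopifnot(inherits(model, "opls_da"))
  ids <- model$metabolite_ids
  if (is.null(subclass)) subclass <- model$subclass
  if (!is.null(names(subclass))) subclass <- subclass[ids]
  subclass <- as.character(subclass)
  subclass[is.na(subclass) | subclass == ""] <- "other"
  counts <- sort(table(subclass[subclass != "other"]), decreasing = TRUE)
  keep_classes <- names(counts)[seq_len(min(top_k, length(counts)))]
  keep <- subclass %in% keep_classes
  o_load <- if (model$n_orthogonal > 0) model$p_orth[, 1] else
    rep(NA_real_, length(ids))
  out <- data.frame(metabolite = ids[keep], subclass = subclass[keep],
                    predictive_loading = model$p[keep],
                    orthogonal_loading = o_load[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
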
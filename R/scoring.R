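#' Youden-index optimal cut-off
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted values, plus -Inf/+Inf sentinels. The returned cut-off maximizes
#' J = sensitivity + specificity - 1 for the rule "intensity strictly above
#' the cut-off is called diseased" (`direction = "above"`, default) or
#' "strictly below" (`direction = "below"`). Ties in J are broken toward
#' higher sensitivity, then toward the lower cut-off.
#'
#' @param values numeric intensities.
#' @param y 0/1 group coding (or labels / metadata).
#' @param direction `"above"` (disease-elevated, default) or `"below"`.
#' @return The optimal cut-off. For constant values J = 0 everywhere and
#'   the +Inf sentinel is returned with a warning.
#' @export
youden_cutoff <- function(values, y, direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (is.data.frame(y) || is.character(y) || is.factor(y)) y <- group_code(y)
  stopifnot(length(values) == length(y))
  if (!any(y == 0) || !any(y == 1)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  v <- sort(unique(values))
  if (length(v) < 2L) {
    warning("constant values: J = 0 at every threshold, returning +Inf")
    return(Inf)
  }
  cand <- c(-Inf, (v[-length(v)] + v[-1]) / 2, Inf)
  j <- sens <- numeric(length(cand))
  for (i in seq_along(cand)) {
    pos <- if (direction == "above") values > cand[i] else values < cand[i]
    sens[i] <- mean(pos[y == 1])
    spec <- mean(!pos[y == 0])
    j[i] <- sens[i] + spec - 1
  }
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[sens[best] == max(sens[best])]
  cand[min(best)]
}

#' Binarize intensities against a cut-off (simple score)
#'
#' The simple score M is 1 when the relative intensity is strictly above
#' the cut-off (default direction) and 0 otherwise — equality scores 0.
#'
#' @param values numeric intensities.
#' @param cutoff finite threshold.
#' @param direction `"above"` (default) or `"below"`.
#' @return Integer 0/1 vector.
#' @export
simple_score <- function(values, cutoff, direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  if (direction == "above") as.integer(values > cutoff)
  else as.integer(values < cutoff)
}

#' Standardized regression weights for the key metabolites
#'
#' All key metabolites are entered simultaneously (enter method) in an OLS
#' of the 0/1 group label on the predictors; coefficients are standardized
#' as beta = b * sd(x) / sd(y), making them unitless weights.
#'
#' @param X samples x keys numeric matrix (named columns) or a
#'   [feature_table()] restricted to the keys. Continuous (typically log)
#'   intensities by default; pass the 0/1 simple-score matrix instead to
#'   weight the binarized scores.
#' @param y 0/1 group coding (or labels / metadata).
#' @return Named numeric vector of standardized beta coefficients.
#' @export
fit_betas <- function(X, y) {
  info <- resolve_xy(X, y)
  X <- info$X; y <- info$y
  if (nrow(X) <= ncol(X) + 2L) {
    stop("fit_betas needs n > number of keys + 2", call. = FALSE)
  }
  d <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = d)
  b <- stats::coef(fit)[-1]
  if (anyNA(b)) {
    stop("singular design: collinear key metabolite(s): ",
         paste(colnames(X)[is.na(b)], collapse = ", "), call. = FALSE)
  }
  sx <- apply(X, 2, stats::sd)
  beta <- unname(b) * sx / stats::sd(y)
  names(beta) <- colnames(X)
  beta
}

#' Lock a metabolite risk score model
#'
#' Freezes the per-key cut-offs, directions, standardized beta weights and
#' the training-set MRS median into an immutable scoring rule
#' MRS = sum(beta_i * M_i). Everything must have been fitted on the
#' discovery set only; applying the model never refits anything.
#'
#' @param keys character vector of key metabolite IDs.
#' @param cutoffs named (or key-ordered) finite cut-off intensities.
#' @param betas named (or key-ordered) standardized beta weights.
#' @param train_median median MRS of the training (discovery) cohort.
#' @param direction per-key scoring direction, `"above"` (default) or
#'   `"below"`, recycled.
#' @return An immutable `mrs_model`.
#' @export
lock_model <- function(keys, cutoffs, betas, train_median,
                       direction = "above") {
  keys <- as.character(keys)
  if (length(keys) < 1L) stop("at least one key metabolite required",
                              call. = FALSE)
  pick <- function(v, what) {
    if (!is.null(names(v))) {
      if (!all(keys %in% names(v))) {
        stop(what, " missing for some keys", call. = FALSE)
      }
      v <- v[keys]
    }
    if (length(v) != length(keys)) {
      stop(what, " must have one value per key", call. = FALSE)
    }
    unname(v)
  }
  cutoffs <- pick(as.numeric(cutoffs), "cutoffs")
  betas <- pick(as.numeric(betas), "betas")
  if (any(!is.finite(cutoffs))) stop("cut-offs must be finite", call. = FALSE)
  if (any(!is.finite(betas))) stop("betas must be finite", call. = FALSE)
  direction <- rep_len(as.character(direction), length(keys))
  stopifnot(all(direction %in% c("above", "below")))
  structure(
    list(keys = keys, cutoffs = cutoffs, betas = betas,
         direction = direction, train_median = as.numeric(train_median),
         locked = TRUE),
    class = "mrs_model"
  )
}

#' @export
print.mrs_model <- function(x, ...) {
  cat("<mrs_model> locked scoring rule MRS = sum(beta_i * M_i)\n")
  for (i in seq_along(x$keys)) {
    cat(sprintf("  %s: beta = %.4f, cut-off = %s (%s -> 1)\n", x$keys[i],
                x$betas[i], format(x$cutoffs[i], digits = 15),
                x$direction[i]))
  }
  cat("  training MRS median =", format(x$train_median, digits = 6), "\n")
  invisible(x)
}

#' Fit an MRS model on a discovery cohort
#'
#' Convenience constructor running the scoring stage end to end on the
#' discovery set: standardized betas from an enter-method OLS on the key
#' metabolites (continuous log2 intensities by default, matching the order
#' in which the score is built: weights first, cut-offs second), Youden
#' cut-offs on the raw relative intensities, then the training MRS median.
#'
#' @param features discovery [feature_table()] of raw intensities.
#' @param meta matching discovery [cohort_metadata()].
#' @param keys key metabolite IDs.
#' @param beta_predictors `"continuous"` (log2 intensities, default) or
#'   `"simple"` (0/1 simple scores) as regression predictors.
#' @param direction per-key scoring direction (default `"above"`).
#' @return A locked `mrs_model`.
#' @export
build_mrs_model <- function(features, meta, keys,
                            beta_predictors = c("continuous", "simple"),
                            direction = "above") {
  beta_predictors <- match.arg(beta_predictors)
  meta <- check_joint(features, meta)
  y <- group_code(meta)
  missing_keys <- setdiff(keys, features$metabolite_ids)
  if (length(missing_keys)) {
    stop("key metabolite(s) absent from feature table: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  raw <- features$intensities[, keys, drop = FALSE]
  direction <- rep_len(direction, length(keys))
  cutoffs <- vapply(seq_along(keys), function(i) {
    youden_cutoff(raw[, i], y, direction = direction[i])
  }, numeric(1))
  names(cutoffs) <- keys
  if (beta_predictors == "continuous") {
    Xb <- if (is.null(features$transform)) log2(raw) else raw
    # orient each predictor along its scoring direction so the weight and
    # the simple score agree in sign for disease-decreased keys
    flip <- direction == "below"
    Xb[, flip] <- -Xb[, flip, drop = FALSE]
  } else {
    Xb <- vapply(seq_along(keys), function(i) {
      simple_score(raw[, i], cutoffs[i], direction[i])
    }, numeric(nrow(raw)))
    colnames(Xb) <- keys
  }
  betas <- fit_betas(Xb, y)
  M <- vapply(seq_along(keys), function(i) {
    simple_score(raw[, i], cutoffs[i], direction[i])
  }, integer(nrow(raw)))
  train_median <- stats::median(drop(matrix(M, nrow = nrow(raw)) %*% betas))
  lock_model(keys, cutoffs, betas, train_median, direction = direction)
}

#' @export
`$<-.mrs_model` <- function(x, name, value) {
  stop("mrs_model is locked and immutable; build a new model instead",
       call. = FALSE)
}

#' @export
`[[<-.mrs_model` <- function(x, i, value) {
  stop("mrs_model is locked and immutable; build a new model instead",
       call. = FALSE)
}

#' Apply a locked MRS model to a cohort
#'
#' Computes per-sample simple scores against the locked cut-offs and the
#' weighted sum MRS = sum(beta_i * M_i). Nothing is refit.
#'
#' @param model a locked `mrs_model`.
#' @param table a [feature_table()] of raw intensities containing the key
#'   metabolite columns.
#' @return A data frame with `sample_id`, one `M_<key>` 0/1 column per key,
#'   and `mrs`.
#' @export
compute_mrs <- function(model, table) {
  stopifnot(inherits(model, "mrs_model"), inherits(table, "feature_table"))
  missing_keys <- setdiff(model$keys, table$metabolite_ids)
  if (length(missing_keys)) {
    stop("feature table is missing key metabolite(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  M <- vapply(seq_along(model$keys), function(i) {
    simple_score(table$intensities[, model$keys[i]], model$cutoffs[i],
                 model$direction[i])
  }, integer(length(table$sample_ids)))
  M <- matrix(M, nrow = length(table$sample_ids))
  out <- data.frame(sample_id = table$sample_ids, M,
                    mrs = drop(M %*% model$betas),
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("M_", model$keys), "mrs")
  out
}

#' Serialize a locked MRS model to JSON
#'
#' Cut-offs and betas are written at full double precision so the locked
#' rule survives a round trip bit for bit.
#'
#' @param model a locked `mrs_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrs_model <- function(model, path) {
  stopifnot(inherits(model, "mrs_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a locked MRS model from JSON
#'
#' @param path path written by [write_mrs_model()].
#' @return An `mrs_model`.
#' @export
read_mrs_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lock_model(x$keys, x$cutoffs, x$betas, x$train_median, x$direction)
}
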
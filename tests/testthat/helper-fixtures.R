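# Shared fixture builders. Everything is generated in code; no data files.

random_feature_table <- function(n = 10, m = 10, seed = 1,
                                 mode = NULL) {
  withr::with_seed(seed, {
    x <- matrix(exp(rnorm(n * m, mean = 16, sd = 0.5)), n, m)
    if (is.null(mode)) mode <- rep_len(c("positive", "negative"), m)
    feature_table(x,
                  sample_ids = sprintf("S%02d", seq_len(n)),
                  metabolite_ids = sprintf("M%02d", seq_len(m)),
                  mode = mode)
  })
}

balanced_y <- function(n) rep(c(0L, 1L), each = n / 2)

# minimal metadata for a feature table and 0/1 coding
meta_for <- function(ft, y, set = "discovery") {
  cohort_metadata(data.frame(
    sample_id = ft$sample_ids,
    group = ifelse(y == 1, "dyslipidemia", "healthy"),
    set = rep_len(set, length(y)),
    stringsAsFactors = FALSE
  ))
}

# tiny two-group matrix with one planted signal column
signal_matrix <- function(n = 60, p = 10, d = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- balanced_y(n)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("V%02d", seq_len(p))))
    X[, 1] <- X[, 1] + d * y
    list(X = X, y = y)
  })
}

# Mann-Whitney AUC by exhaustive pair counting (ties count 1/2)
auc_by_pairs <- function(x, y) {
  pos <- x[y == 1]; neg <- x[y == 0]
  gt <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# Youden J for the "strictly above" rule at a given threshold
youden_j <- function(values, y, cut, direction = "above") {
  pos <- if (direction == "above") values > cut else values < cut
  mean(pos[y == 1]) + mean(!pos[y == 0]) - 1
}
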
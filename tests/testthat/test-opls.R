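test_that("a noiseless separable predictor gives R2Y near 1", {
  y <- balanced_y(20)
  X <- cbind(a = y, b = 2 * y + 1)           # y exactly linear in X
  fit <- fit_opls_da(X, y, n_orthogonal = 0, scaling = "none")
  expect_gt(fit$R2Y, 0.99)
  cv <- cross_validate_q2(X, y, n_orthogonal = 0, k_folds = 5,
                          scaling = "none")
  expect_gt(cv$Q2Y, 0.9)
})

test_that("with no orthogonal components the fit matches the analytic PLS1 solution", {
  withr::with_seed(4, {
    X <- matrix(rnorm(24), 6, 4)
    y <- c(0, 1, 0, 1, 0, 1)
  })
  fit <- fit_opls_da(X, y, n_orthogonal = 0, scaling = "uv")
  # closed form: w proportional to Xs' yc on the scaled matrix
  Xs <- scale(X)
  yc <- y - mean(y)
  w <- drop(crossprod(Xs, yc)); w <- w / sqrt(sum(w^2))
  tt <- drop(Xs %*% w)
  cc <- sum(yc * tt) / sum(tt^2)
  expect_equal(unname(fit$fitted), unname(tt * cc + mean(y)),
               tolerance = 1e-8)
  expect_equal(abs(unname(fit$w)), abs(unname(w)), tolerance = 1e-8)
})

test_that("orthogonal scores are uncorrelated with y and the predictive score", {
  for (s in 1:8) {
    dat <- signal_matrix(n = 40, p = 15, d = 1.5, seed = s)
    fit <- fit_opls_da(dat$X, dat$y, n_orthogonal = 2, auto_stop = FALSE)
    for (a in seq_len(fit$n_orthogonal)) {
      expect_lt(abs(cor(fit$t_orth[, a], dat$y)), 1e-8)
      expect_lt(abs(cor(fit$t_orth[, a], fit$t)), 1e-8)
    }
  }
})

test_that("degenerate inputs are handled: one class errors, constant column dropped", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_opls_da(X, rep(1, 10)), "both classes")
  X[, 2] <- 7
  colnames(X) <- paste0("m", 1:4)
  expect_warning(fit <- fit_opls_da(X, balanced_y(10), n_orthogonal = 0),
                 "constant metabolite")
  expect_equal(length(fit$w), 3)
})

test_that("VIP normalization, symmetry and single-variable cases hold", {
  y <- balanced_y(12)
  expect_equal(unname(vip_scores(
    fit_opls_da(matrix(rnorm(12) + y, 12, 1), y, n_orthogonal = 0))), 1)

  withr::with_seed(9, x1 <- rnorm(12) + 2 * y)
  X <- cbind(a = x1, b = x1, c = rnorm(12))
  vip <- vip_scores(fit_opls_da(X, y, n_orthogonal = 0))
  expect_equal(vip[["a"]], vip[["b"]], tolerance = 1e-10)

  for (s in 1:10) {
    dat <- signal_matrix(n = 30, p = 12, d = 1, seed = 100 + s)
    vip <- vip_scores(fit_opls_da(dat$X, dat$y))
    expect_equal(mean(vip^2), 1, tolerance = 1e-6)
  }
})

test_that("Q2Y never exceeds R2Y on matched data and folds", {
  for (s in 1:20) {
    dat <- signal_matrix(n = 28, p = 10, d = runif(1, 0, 2), seed = 200 + s)
    fit <- suppressWarnings(fit_opls_da(dat$X, dat$y))
    cv <- cross_validate_q2(dat$X, dat$y)
    expect_lte(cv$Q2Y, fit$R2Y + 1e-9)
  }
})

test_that("CV-ANOVA returns p = 1 without cross-validated evidence and detects strong signal", {
  # pure noise, tiny n: PRESS >= SS -> no evidence
  withr::with_seed(31, {
    X <- matrix(rnorm(12 * 6), 12, 6)
    y <- balanced_y(12)
  })
  ca <- cv_anova(X, y, n_orthogonal = 0, k_folds = 2)
  expect_gte(ca$PRESS, ca$SS)
  expect_equal(ca$p, 1)

  dat <- signal_matrix(n = 100, p = 30, d = 2, seed = 32)
  ca2 <- cv_anova(dat$X, dat$y)
  expect_lt(ca2$p, 0.05)
  expect_gt(ca2$Q2Y, 0)
})

test_that("permutation test brackets its empirical p as designed", {
  # strong signal: observed Q2Y beats every permutation -> p at its floor
  dat <- signal_matrix(n = 40, p = 10, d = 3, seed = 41)
  rep_strong <- permutation_test(dat$X, dat$y, n_permutations = 25, seed = 2)
  expect_equal(rep_strong$p, 1 / 26)
  expect_equal(rep_strong$n_permutations, 25)
  expect_true(all(rep_strong$Q2Y_perm < rep_strong$Q2Y_obs))
  expect_lt(rep_strong$Q2Y_intercept, rep_strong$Q2Y_obs)

  # X aligned with a different labelling: permutations often do better
  withr::with_seed(43, {
    z <- sample(balanced_y(40))
    X2 <- matrix(rnorm(40 * 8), 40, 8)
    X2[, 1] <- X2[, 1] + 3 * z
    y2 <- balanced_y(40)
  })
  rep_null <- permutation_test(X2, y2, n_permutations = 39, seed = 3)
  expect_gte(rep_null$p, 1 / 40)
  expect_lte(rep_null$p, 1)
  expect_gt(rep_null$p, 0.2)

  expect_error(permutation_test(dat$X, dat$y, n_permutations = 10),
               "at least 20")
})

test_that("loading summary groups by the most frequent subclasses", {
  sim <- simulate_cohort(sim_config(n_per_group_per_set = 25,
                                    n_metabolites_pos = 80,
                                    n_metabolites_neg = 10,
                                    key_effects = data.frame(index = 2,
                                                             effect = 2),
                                    seed = 51))
  d <- split_sets(sim$features, sim$meta)$discovery
  ftl <- log_transform(d$features)
  pos <- subset_feature_table(ftl, metabolites = which(ftl$mode == "positive"))
  fit <- fit_opls_da(pos, d$meta)

  ls3 <- loading_summary(fit, top_k = 3)
  expect_setequal(unique(ls3$subclass),
                  c("acylcarnitine", "amino acid", "lysophosphatidylcholine"))
  # subclass row counts match the annotation frequencies
  expect_equal(as.vector(table(ls3$subclass)[c("acylcarnitine")]), 30)

  ls1 <- loading_summary(fit, top_k = 1)
  expect_equal(unique(ls1$subclass), "acylcarnitine")

  # disease-elevated planted metabolite loads positively (healthy=0/dys=1)
  expect_gt(ls3$predictive_loading[ls3$metabolite == "P002"], 0)
})
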
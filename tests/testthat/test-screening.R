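test_that("univariate screen: exact null gives p = 1, planted signal passes FDR", {
  # disease rows literally duplicate healthy rows: mean difference is zero
  withr::with_seed(61, half <- matrix(exp(rnorm(5 * 8, 16)), 5, 8))
  ft <- feature_table(rbind(half, half),
                      sample_ids = sprintf("S%02d", 1:10),
                      metabolite_ids = sprintf("M%02d", 1:8))
  univ0 <- univariate_screen(log_transform(ft), meta_for(ft, balanced_y(10)))
  expect_true(all(abs(univ0$t) < 1e-12))
  expect_true(all(univ0$p > 0.999))

  sim <- simulate_cohort(sim_config(n_per_group_per_set = 50,
                                    n_metabolites_pos = 20,
                                    n_metabolites_neg = 10,
                                    key_effects = data.frame(index = 3,
                                                             effect = 2),
                                    seed = 62))
  d <- split_sets(sim$features, sim$meta)$discovery
  univ <- univariate_screen(log_transform(d$features), d$meta)
  expect_lt(univ$q[univ$metabolite == "P003"], 0.05)
  expect_gt(univ$log2_fc[univ$metabolite == "P003"], 0)
  # q monotone in p
  expect_true(all(diff(univ$q[order(univ$p)]) >= -1e-12))
})

test_that("Benjamini-Hochberg q-values match the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  p <- c(0.001, 0.2, 0.8, 0.9)
  expect_true(all(fdr_adjust(p, "storey") <= fdr_adjust(p, "BH") + 1e-12))
})

test_that("zero-variance metabolites are reported, not fatal", {
  x <- matrix(exp(rnorm(40, 16)), 10, 4,
              dimnames = list(sprintf("S%02d", 1:10), sprintf("M%02d", 1:4)))
  x[, 2] <- 5
  ft <- feature_table(x)
  expect_warning(univ <- univariate_screen(log_transform(ft),
                                           meta_for(ft, balanced_y(10))),
                 "zero-variance")
  expect_equal(univ$p[2], 1)
})

test_that("major-metabolite filter reproduces set logic, incl. the study's counts", {
  # 11 positive + 4 negative metabolites at VIP >= 1.5, 3 positive ones
  # failing q < 0.05 -> 12 major metabolites
  ids <- c(sprintf("P%02d", 1:20), sprintf("N%02d", 1:10))
  univ <- data.frame(metabolite = ids,
                     mode = rep(c("positive", "negative"), c(20, 10)),
                     q = 1, stringsAsFactors = FALSE)
  vip <- setNames(rep(0.5, 30), ids)
  vip[sprintf("P%02d", 1:11)] <- 1.8        # VIP-passing positive
  vip[sprintf("N%02d", 1:4)] <- 2.1         # VIP-passing negative
  univ$q[univ$metabolite %in% sprintf("P%02d", 1:8)] <- 0.01   # 3 fail q
  univ$q[univ$metabolite %in% sprintf("N%02d", 1:4)] <- 0.001
  univ$q[univ$metabolite %in% sprintf("P%02d", 15:20)] <- 0.01 # q w/o VIP
  major <- select_major(univ, vip)
  expect_length(major, 12)
  expect_setequal(major, c(sprintf("P%02d", 1:8), sprintf("N%02d", 1:4)))

  expect_length(select_major(univ, vip, vip_threshold = Inf), 0)

  # brute-force oracle on a random fixture
  withr::with_seed(63, {
    univ2 <- data.frame(metabolite = sprintf("M%02d", 1:20),
                        mode = "positive", q = runif(20),
                        stringsAsFactors = FALSE)
    vip2 <- setNames(runif(20, 0, 3), univ2$metabolite)
  })
  expect_setequal(select_major(univ2, vip2),
                  univ2$metabolite[vip2 >= 1.5 & univ2$q < 0.05])
})

test_that("stepwise selection enters true signal and excludes exact duplicates", {
  dat <- signal_matrix(n = 60, p = 10, d = 2, seed = 71)
  res <- stepwise_select(dat$X, dat$y)
  expect_true("V01" %in% res$survivors)

  # a duplicated column has tolerance 0 once its twin is in
  Xdup <- cbind(dat$X[, 1:4], V01b = dat$X[, 1])
  res2 <- stepwise_select(Xdup, dat$y)
  entered <- intersect(c("V01", "V01b"), res2$survivors)
  expect_length(entered, 1)
  other <- setdiff(c("V01", "V01b"), entered)
  expect_true(other %in% res2$excluded$id)
  expect_equal(res2$excluded$reason[res2$excluded$id == other],
               "multicollinearity")

  expect_length(stepwise_select(dat$X, dat$y, p_enter = 0)$survivors, 0)
  expect_error(stepwise_select(dat$X[1:8, ], dat$y[1:8]),
               "n > candidates")
})

test_that("the VIF rule excludes a near-collinear twin once one member enters", {
  withr::with_seed(72, {
    y <- balanced_y(80)
    z <- rnorm(80) + 1.5 * y
    X <- cbind(A = z + 0.15 * rnorm(80), B = z + 0.15 * rnorm(80),
               C = rnorm(80))
  })
  res <- stepwise_select(X, y, collinearity_rule = "vif")
  entered <- intersect(c("A", "B"), res$survivors)
  expect_length(entered, 1)
  expect_true(setdiff(c("A", "B"), entered) %in% res$excluded$id)
  # the lenient tolerance rule keeps both candidates eligible
  res_tol <- stepwise_select(X, y, collinearity_rule = "tolerance")
  expect_length(res_tol$excluded$id, 0)
})

test_that("ROC filter: exact AUCs, orientation, and null false-positive rate", {
  rf <- roc_filter(cbind(perfect = c(1, 2, 3, 4, 5, 6)),
                   c(0, 0, 0, 1, 1, 1))
  expect_equal(rf$stats$auc, 1)
  expect_true("perfect" %in% rf$keys)

  rf2 <- roc_filter(cbind(m = c(1, 3, 2, 4)), c(0, 0, 1, 1))
  expect_equal(rf2$stats$auc, 0.75)   # 3 of 4 concordant pairs

  # identical distributions: kept with probability ~ alpha
  kept <- vapply(1:200, function(s) {
    withr::with_seed(7000 + s, x <- rnorm(100))
    length(roc_filter(cbind(m = x), balanced_y(100))$keys) > 0
  }, logical(1))
  expect_gte(mean(kept), 0.01)
  expect_lte(mean(kept), 0.10)
})

test_that("clinical comparison reproduces the chi-squared sex test and adjustment logic", {
  # sex split 33/17 vs 36/13 is not significant
  meta <- cohort_metadata(data.frame(
    sample_id = sprintf("S%03d", 1:99),
    group = rep(c("healthy", "dyslipidemia"), c(50, 49)),
    set = "discovery",
    sex = c(rep("male", 33), rep("female", 17),
            rep("male", 36), rep("female", 13)),
    stringsAsFactors = FALSE
  ))
  cc <- clinical_compare(meta, adjust_for = character())
  expect_equal(cc$test, "chi_squared")
  expect_gt(cc$p_unadjusted, 0.05)

  # no confounding: adjusted p tracks unadjusted p
  withr::with_seed(81, {
    n <- 100; y <- balanced_y(n)
    age <- rnorm(n, 50, 5)                  # independent of group
    marker <- rnorm(n) + 1.2 * y
    meta2 <- cohort_metadata(data.frame(
      sample_id = sprintf("S%03d", 1:n),
      group = ifelse(y == 1, "dyslipidemia", "healthy"),
      set = "discovery", age = age, marker = marker))
  })
  cc2 <- clinical_compare(meta2, adjust_for = "age")
  row <- cc2[cc2$variable == "marker", ]
  expect_lt(row$p_unadjusted, 0.01)
  expect_lt(abs(log10(row$p_adjusted) - log10(row$p_unadjusted)), 1.5)
  expect_true(is.na(cc2$p_adjusted[cc2$variable == "age"]))
})

test_that("adjustment removes confounder-driven significance", {
  hits <- vapply(1:50, function(s) {
    withr::with_seed(8000 + s, {
      n <- 100; y <- balanced_y(n)
      age <- rnorm(n, 45, 5) + 8 * y          # age differs by group
      marker <- 2 * age + rnorm(n, 0, 5)      # marker driven by age only
      meta <- cohort_metadata(data.frame(
        sample_id = sprintf("S%03d", 1:n),
        group = ifelse(y == 1, "dyslipidemia", "healthy"),
        set = "discovery", age = age, marker = marker))
    })
    cc <- clinical_compare(meta, adjust_for = "age")
    row <- cc[cc$variable == "marker", ]
    (row$p_unadjusted < 0.05) && (row$p_adjusted > 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
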
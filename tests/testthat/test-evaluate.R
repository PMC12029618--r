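scenario_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- make_paper_like_scenario(seed = 5)
      halves <- split_sets(sc$features, sc$meta)
      model <- build_mrs_model(halves$discovery$features,
                               halves$discovery$meta, sc$truth$keys)
      suite <- fit_model_suite(halves$discovery$features,
                               halves$discovery$meta, model)
      cache <<- list(sc = sc, halves = halves, model = model, suite = suite)
    }
    cache
  }
})

test_that("the model suite contains one model per key plus three composites", {
  fx <- scenario_fixture()
  expect_length(fx$suite$models, length(fx$model$keys) + 3)
  expect_true(all(c("lipid_profile", "mrs", "mrs_lipid") %in%
                    names(fx$suite$models)))

  # the MRS model's score is the raw MRS, no refitting
  sc_disc <- score_model_suite(fx$suite, fx$halves$discovery$features,
                               fx$halves$discovery$meta)
  expect_identical(sc_disc$mrs,
                   compute_mrs(fx$model,
                               fx$halves$discovery$features)$mrs)
  expect_error(fit_model_suite(fx$halves$discovery$features,
                               fx$halves$discovery$meta, fx$model,
                               lipid_vars = c("tg", "nope")),
               "missing lipid")
})

test_that("roc_report matches exhaustive pair counting and handles edge cases", {
  r <- roc_report(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)

  expect_equal(roc_report(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)

  for (s in 1:20) {
    withr::with_seed(300 + s, {
      n <- sample(c(12, 20, 30), 1)
      y <- balanced_y(n)
      x <- round(rnorm(n), 1)
    })
    expect_equal(roc_report(x, y)$auc, auc_by_pairs(x, y))
  }

  rc <- suppressWarnings(roc_report(rep(1, 10), balanced_y(10)))
  expect_equal(rc$auc, 0.5)
  expect_equal(rc$p, 1)
  # CI contains the AUC
  fx <- scenario_fixture()
  ev <- evaluate_models(fx$suite, fx$halves$replication$features,
                        fx$halves$replication$meta)
  expect_true(all(ev$ci_lower <= ev$auc & ev$auc <= ev$ci_upper))
  expect_true(all(ev$accuracy >= 0 & ev$accuracy <= 1))
})

test_that("the combined model is at least as good as its parts on discovery", {
  fx <- scenario_fixture()
  ev <- evaluate_models(fx$suite, fx$halves$discovery$features,
                        fx$halves$discovery$meta)
  auc <- setNames(ev$auc, ev$model)
  expect_gte(auc["mrs_lipid"], max(auc["mrs"], auc["lipid_profile"]) - 0.02)
})

test_that("median-split regrouping reports counts and percentages consistently", {
  # fixture engineered to the printed confusion: 40 re-assigned healthy of
  # whom 31 truly healthy; 60 re-assigned dyslipidemia of whom 41 diseased
  mrs <- c(rep(0, 40), rep(1, 60))
  true_grp <- c(rep("healthy", 31), rep("dyslipidemia", 9),
                rep("healthy", 19), rep("dyslipidemia", 41))
  meta <- cohort_metadata(data.frame(sample_id = sprintf("S%03d", 1:100),
                                     group = true_grp, set = "replication",
                                     stringsAsFactors = FALSE))
  rg <- regroup_by_mrs(mrs, meta, threshold = 0.5)
  expect_equal(unname(rg$n_regrouped), c(40, 60))
  expect_equal(sum(rg$counts), 100)
  expect_equal(unname(rg$percent_correct["healthy"]), 77.5)
  expect_equal(unname(rg$percent_correct["dyslipidemia"]),
               100 * 41 / 60)
  # percentages recompute exactly from the counts
  expect_equal(unname(rg$percent_correct),
               unname(100 * diag(rg$counts) / rowSums(rg$counts)))

  # degenerate: every score below threshold -> everyone re-assigned healthy
  rg0 <- regroup_by_mrs(rep(0, 10), meta_for(random_feature_table(10, 2),
                                             balanced_y(10)),
                        threshold = 0.5)
  expect_equal(unname(rg0$n_regrouped), c(10, 0))
  expect_equal(unname(rg0$percent_correct["healthy"]), 50)
})

test_that("samples at the threshold are re-assigned to the dyslipidemia group", {
  meta <- meta_for(random_feature_table(4, 2), c(0, 1, 0, 1))
  rg <- regroup_by_mrs(c(0.1, 0.52, 0.52, 0.9), meta, threshold = 0.52)
  expect_equal(unname(rg$predicted),
               c("healthy", "dyslipidemia", "dyslipidemia", "dyslipidemia"))
})

test_that("regrouped OPLS-DA distinguishes informative from random labels", {
  fx <- scenario_fixture()
  repl <- fx$halves$replication
  scores <- compute_mrs(fx$model, repl$features)
  rg <- regroup_by_mrs(scores, repl$meta, fx$model$train_median)
  ro <- regrouped_opls(log_transform(repl$features), rg$predicted)
  expect_named(ro, c("positive", "negative"))
  expect_lt(ro$positive$p_cvanova, 0.05)

  # identical labels to truth reproduce the plain analysis
  ro_true <- regrouped_opls(log_transform(repl$features),
                            group_code(repl$meta))
  direct <- cv_anova(subset_feature_table(
    log_transform(repl$features),
    metabolites = which(repl$features$mode == "positive")),
    group_code(repl$meta))
  expect_equal(ro_true$positive$Q2Y, direct$Q2Y, tolerance = 1e-12)
})

test_that("lock-down: replication labels cannot leak into the locked models", {
  fx <- scenario_fixture()
  repl <- fx$halves$replication
  model_before <- unclass(fx$model)
  coef_before <- lapply(fx$suite$models, function(m) m$coef)
  scores_before <- score_model_suite(fx$suite, repl$features, repl$meta)

  mutated <- repl$meta
  mutated$group <- rev(mutated$group)
  scores_after <- score_model_suite(fx$suite, repl$features, mutated)

  expect_identical(unclass(fx$model), model_before)
  expect_identical(lapply(fx$suite$models, function(m) m$coef), coef_before)
  drop_id <- function(d) d[setdiff(names(d), "sample_id")]
  expect_identical(drop_id(scores_after), drop_id(scores_before))
})
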
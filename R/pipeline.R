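#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end MRS pipeline with validated
#' defaults: VIP >= 1.5 and q < 0.05 for the major-metabolite filter,
#' stepwise entry/removal at p 0.05/0.10, ROC significance at alpha 0.05,
#' unit-variance scaling with one orthogonal component and 7-fold
#' cross-validation for OPLS-DA.
#'
#' @param simulation a [sim_config()], the string `"paper_like"` for
#'   [make_paper_like_scenario()], or `NULL` when reading files.
#' @param features_path,annotation_path,meta_path input CSVs (used when
#'   `simulation` is `NULL`).
#' @param seed integer seed for simulation/permutations.
#' @param log_base,pseudocount log-transform settings ([log_transform()]).
#' @param scaling,n_orthogonal,k_folds OPLS-DA settings.
#' @param vip_threshold,q_threshold,fdr_method major-metabolite filter.
#' @param p_enter,p_remove,collinearity_rule stepwise settings.
#' @param alpha ROC key-metabolite significance level.
#' @param stepwise_on_log run stepwise selection on log intensities
#'   (default `TRUE`) or raw.
#' @param beta_predictors `"continuous"` or `"simple"`
#'   (see [build_mrs_model()]).
#' @param lipid_vars lipid-profile metadata columns.
#' @param direction_by_auc orient each key's scoring direction by its ROC
#'   AUC (default `TRUE`): disease-decreased keys (AUC < 0.5) score 1 below
#'   their cut-off. With `FALSE` every key uses the fixed "above -> 1" rule,
#'   which is degenerate for disease-decreased keys.
#' @param n_permutations permutations for the re-grouped OPLS diagnostic
#'   (0 = skip).
#' @param regroup_median `"discovery"` (locked training median, default) or
#'   `"replication"` (the replication cohort's own median).
#' @param output_dir optional directory for JSON artifacts.
#' @return A validated `run_config` list.
#' @export
run_config <- function(simulation = "paper_like",
                       features_path = NULL, annotation_path = NULL,
                       meta_path = NULL, seed = 1L,
                       log_base = 2, pseudocount = 0,
                       scaling = "uv", n_orthogonal = 1, k_folds = 7,
                       vip_threshold = 1.5, q_threshold = 0.05,
                       fdr_method = "BH",
                       p_enter = 0.05, p_remove = 0.10,
                       collinearity_rule = "tolerance",
                       alpha = 0.05, stepwise_on_log = TRUE,
                       beta_predictors = "continuous",
                       direction_by_auc = TRUE,
                       lipid_vars = c("tg", "hdl_c", "ldl_c", "tc"),
                       n_permutations = 0,
                       regroup_median = "discovery",
                       output_dir = NULL) {
  bad <- function(msg) stop("config validation error: ", msg, call. = FALSE)
  if (!(is.numeric(q_threshold) && q_threshold > 0 && q_threshold <= 1)) {
    bad("q_threshold must lie in (0, 1]")
  }
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1)) {
    bad("alpha must lie in (0, 1)")
  }
  if (!(is.numeric(vip_threshold) && vip_threshold >= 0)) {
    bad("vip_threshold must be non-negative")
  }
  if (!(p_enter >= 0 && p_enter <= 1 && p_remove >= 0 && p_remove <= 1)) {
    bad("p_enter and p_remove must lie in [0, 1]")
  }
  if (p_remove < p_enter) bad("p_remove must be >= p_enter")
  if (k_folds < 2) bad("k_folds must be at least 2")
  if (n_orthogonal < 0) bad("n_orthogonal must be non-negative")
  if (is.null(simulation) &&
      (is.null(features_path) || is.null(meta_path))) {
    bad("either a simulation or features_path + meta_path is required")
  }
  if (!regroup_median %in% c("discovery", "replication")) {
    bad("regroup_median must be 'discovery' or 'replication'")
  }
  structure(
    list(simulation = simulation, features_path = features_path,
         annotation_path = annotation_path, meta_path = meta_path,
         seed = as.integer(seed), log_base = log_base,
         pseudocount = pseudocount, scaling = scaling,
         n_orthogonal = n_orthogonal, k_folds = k_folds,
         vip_threshold = vip_threshold, q_threshold = q_threshold,
         fdr_method = fdr_method, p_enter = p_enter, p_remove = p_remove,
         collinearity_rule = collinearity_rule, alpha = alpha,
         stepwise_on_log = stepwise_on_log,
         beta_predictors = beta_predictors,
         direction_by_auc = direction_by_auc, lipid_vars = lipid_vars,
         n_permutations = n_permutations, regroup_median = regroup_median,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$simulation) && is.list(args$simulation)) {
    args$simulation <- do.call(sim_config, args$simulation)
  }
  do.call(run_config, args)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full MRS pipeline
#'
#' Executes the complete two-phase analysis: obtain the cohort (simulate or
#' load), split into discovery and replication, per-ionization-mode OPLS-DA
#' with cross-validated Q2Y and CV-ANOVA, univariate screen with FDR
#' q-values, major-metabolite filter (VIP and q), stepwise key-metabolite
#' selection with multicollinearity exclusion, ROC key filter, locked MRS
#' construction (standardized betas, Youden cut-offs, training median),
#' model-suite evaluation on discovery and replication, and the MRS
#' median-split re-grouping of the replication set with its own OPLS-DA
#' check. When `output_dir` is set, JSON artifacts stamped with the seed
#' and a config hash are written; reruns with the same config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return A list with elements `opls` (per mode), `univariate`, `screen`,
#'   `mrs_model`, `evaluation` (`discovery`, `replication`), `regroup`,
#'   `regrouped_opls`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- with_stage("input", {
    if (is.null(config$simulation)) {
      list(features = read_feature_table(config$features_path,
                                         annotation = config$annotation_path),
           meta = read_cohort_metadata(config$meta_path))
    } else if (identical(config$simulation, "paper_like")) {
      make_paper_like_scenario(seed = config$seed)
    } else {
      simulate_cohort(config$simulation)
    }
  })
  halves <- with_stage("split", split_sets(cohort$features, cohort$meta))
  disc <- halves$discovery; repl <- halves$replication
  disc_log <- with_stage("transform",
                         log_transform(disc$features, base = config$log_base,
                                       pseudocount = config$pseudocount))
  y_disc <- group_code(disc$meta)

  modes <- intersect(c("positive", "negative"),
                     unique(disc$features$mode))
  opls <- with_stage("multivariate", {
    out <- lapply(modes, function(md) {
      ft <- subset_feature_table(disc_log,
                                 metabolites = which(disc_log$mode == md))
      fit <- suppressWarnings(
        fit_opls_da(ft, y_disc, n_orthogonal = config$n_orthogonal,
                    scaling = config$scaling))
      ca <- cv_anova(ft, y_disc, n_orthogonal = config$n_orthogonal,
                     k_folds = config$k_folds, scaling = config$scaling)
      list(model = fit, R2Y = fit$R2Y, Q2Y = ca$Q2Y, p_cvanova = ca$p,
           vip = vip_scores(fit))
    })
    names(out) <- modes
    out
  })
  vip_all <- do.call(c, lapply(opls, `[[`, "vip"))
  names(vip_all) <- sub("^(positive|negative)\\.", "", names(vip_all))

  univ <- with_stage("univariate",
                     univariate_screen(disc_log, disc$meta,
                                       fdr_method = config$fdr_method))
  major <- with_stage("select_major",
                      select_major(univ, vip_all,
                                   vip_threshold = config$vip_threshold,
                                   q_threshold = config$q_threshold))
  if (!length(major)) {
    stop("pipeline stage 'select_major' failed: no metabolite passed the ",
         "VIP/q filter", call. = FALSE)
  }
  step_tbl <- if (config$stepwise_on_log) disc_log else disc$features
  step <- with_stage("stepwise", {
    stepwise_select(subset_feature_table(step_tbl, metabolites = major),
                    y_disc, p_enter = config$p_enter,
                    p_remove = config$p_remove,
                    collinearity_rule = config$collinearity_rule)
  })
  if (!length(step$survivors)) {
    stop("pipeline stage 'stepwise' failed: no survivors", call. = FALSE)
  }
  rocf <- with_stage("roc_filter", {
    roc_filter(subset_feature_table(disc$features,
                                    metabolites = step$survivors),
               y_disc, alpha = config$alpha)
  })
  if (!length(rocf$keys)) {
    stop("pipeline stage 'roc_filter' failed: no key metabolite reached ",
         "ROC significance", call. = FALSE)
  }
  mrs_model <- with_stage("scoring", {
    dirs <- if (config$direction_by_auc) {
      key_auc <- rocf$stats$auc[match(rocf$keys, rocf$stats$metabolite)]
      ifelse(key_auc >= 0.5, "above", "below")
    } else "above"
    build_mrs_model(disc$features, disc$meta, rocf$keys,
                    beta_predictors = config$beta_predictors,
                    direction = dirs)
  })
  suite <- with_stage("evaluate",
                      fit_model_suite(disc$features, disc$meta, mrs_model,
                                      lipid_vars = config$lipid_vars))
  eval_disc <- with_stage("evaluate",
                          evaluate_models(suite, disc$features, disc$meta))
  eval_repl <- with_stage("evaluate",
                          evaluate_models(suite, repl$features, repl$meta))
  repl_scores <- with_stage("regroup", compute_mrs(mrs_model, repl$features))
  threshold <- if (config$regroup_median == "discovery") {
    mrs_model$train_median
  } else {
    stats::median(repl_scores$mrs)
  }
  regroup <- with_stage("regroup",
                        regroup_by_mrs(repl_scores, repl$meta, threshold))
  repl_log <- with_stage("regrouped_opls",
                         log_transform(repl$features, base = config$log_base,
                                       pseudocount = config$pseudocount))
  re_opls <- with_stage("regrouped_opls", {
    regrouped_opls(repl_log, regroup$predicted,
                   n_orthogonal = config$n_orthogonal,
                   k_folds = config$k_folds, scaling = config$scaling,
                   n_permutations = config$n_permutations,
                   seed = config$seed)
  })

  result <- list(
    opls = opls, univariate = univ,
    screen = list(major = major, survivors = step$survivors,
                  excluded = step$excluded, keys = rocf$keys,
                  roc_stats = rocf$stats),
    mrs_model = mrs_model, model_suite = suite,
    evaluation = list(discovery = eval_disc, replication = eval_repl),
    regroup = regroup, regrouped_opls = re_opls,
    truth = cohort$truth, config = config,
    config_hash = config_hash(config)
  )
  if (!is.null(config$output_dir)) write_artifacts(result, config$output_dir)
  result
}

config_hash <- function(config) {
  # rolling hash over the canonical JSON of the analysis settings (the
  # output location is an execution detail, not part of the analysis)
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  if (inherits(cfg$simulation, "sim_config")) {
    cfg$simulation <- unclass(cfg$simulation)
  }
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = result$config$seed, config_hash = result$config_hash)
  wj <- function(x, file) {
    jsonlite::write_json(c(stamp, x), file.path(dir, file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  wj(list(modes = lapply(result$opls, function(o) {
    list(R2Y = o$R2Y, Q2Y = o$Q2Y, p_cvanova = o$p_cvanova,
         vip = as.list(o$vip))
  })), "opls_report.json")
  wj(list(major = result$screen$major, survivors = result$screen$survivors,
          excluded = result$screen$excluded,
          keys = result$screen$keys, roc = result$screen$roc_stats),
     "screen.json")
  write_mrs_model(result$mrs_model, file.path(dir, "mrs_model.json"))
  wj(list(discovery = result$evaluation$discovery,
          replication = result$evaluation$replication), "evaluation.json")
  wj(list(threshold = result$regroup$threshold,
          counts = as.data.frame(result$regroup$counts),
          percent_correct = as.list(result$regroup$percent_correct),
          regrouped_opls = lapply(result$regrouped_opls, function(o) {
            list(R2Y = o$R2Y, Q2Y = o$Q2Y, p_cvanova = o$p_cvanova)
          })), "regroup.json")
  invisible(dir)
}
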
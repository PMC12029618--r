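#' Default clinical covariate specification
#'
#' Per-covariate healthy-group mean, within-group SD and dyslipidemia-group
#' shift used by [simulate_cohort()]. Defaults reproduce the clinical table
#' of a two-phase dyslipidemia case/control study (age +7.6 y, body weight
#' +7.1 kg, BMI +3.3 kg/m2, glucose +29.3 mg/dL, modest lipid-profile
#' shifts). SDs are reconstructed from reported standard errors at n = 50.
#'
#' @return A data frame with columns `name`, `mean_healthy`, `sd`, `delta`
#'   (dyslipidemia minus healthy mean).
#' @export
default_covariate_effects <- function() {
  data.frame(
    name         = c("age", "weight", "bmi", "sbp", "dbp", "glucose",
                     "tg", "hdl_c", "ldl_c", "tc", "ast", "alt"),
    mean_healthy = c(44.8, 68.9, 24.5, 122.8, 76.2, 96.1,
                     140.3, 49.0, 107.0, 201.1, 23.7, 23.9),
    sd           = c(5.2, 10.8, 3.0, 11.1, 9.9, 9.8,
                     77.8, 10.1, 41.3, 33.0, 11.1, 14.1),
    delta        = c(7.6, 7.1, 3.3, 10.3, 3.8, 29.3,
                     35.1, -3.0, -4.8, -26.5, 14.2, 15.4),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic case/control cohorts
#'
#' Describes a two-group (healthy/dyslipidemia), two-set
#' (discovery/replication) untargeted-metabolomics cohort with log-normal
#' intensities: log intensities are Gaussian with mean `base_log_mean` and
#' SD `base_log_sd`, planted differential metabolites are shifted in the
#' dyslipidemia group by `effect` SD units on the log scale, and collinear
#' pairs share a latent factor plus independent noise so their empirical
#' correlation approaches the target.
#'
#' @param n_per_group_per_set samples per group per set (default 50).
#' @param n_metabolites_pos positive-mode metabolite count (default 128).
#' @param n_metabolites_neg negative-mode metabolite count (default 69).
#' @param key_effects data frame with columns `index` (column index into the
#'   combined positive-then-negative metabolite panel) and `effect` (signed
#'   shift in SD units on the log scale; positive = disease-elevated).
#' @param collinear_pairs data frame with columns `i`, `j`, `r` (target
#'   correlation, |r| < 1).
#' @param base_log_mean mean of log intensities (default 16.5, i.e. median
#'   intensity around 1.5e7 instrument units, so cut-offs have the
#'   magnitude seen on Orbitrap relative intensities).
#' @param base_log_sd SD of log intensities (default 0.6).
#' @param covariate_effects data frame as [default_covariate_effects()].
#' @param male_prob length-2 probability of male sex in (healthy,
#'   dyslipidemia) groups.
#' @param heavy_tails if `TRUE`, draw log intensities from a scaled t(5)
#'   instead of a Gaussian.
#' @param seed integer RNG seed; required for reproducibility.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group_per_set = 50,
                       n_metabolites_pos = 128,
                       n_metabolites_neg = 69,
                       key_effects = NULL,
                       collinear_pairs = NULL,
                       base_log_mean = 16.5,
                       base_log_sd = 0.6,
                       covariate_effects = default_covariate_effects(),
                       male_prob = c(0.66, 0.735),
                       heavy_tails = FALSE,
                       seed = 1L) {
  stopifnot(n_per_group_per_set > 0, n_metabolites_pos > 0,
            n_metabolites_neg > 0, base_log_sd > 0)
  m <- n_metabolites_pos + n_metabolites_neg
  if (is.null(key_effects)) {
    key_effects <- data.frame(index = integer(), effect = numeric())
  }
  key_effects <- as.data.frame(key_effects)
  if (nrow(key_effects)) {
    stopifnot(all(c("index", "effect") %in% names(key_effects)),
              all(key_effects$index >= 1), all(key_effects$index <= m),
              all(is.finite(key_effects$effect)))
    if (anyDuplicated(key_effects$index)) {
      stop("config error: duplicate key_effects index", call. = FALSE)
    }
  }
  if (is.null(collinear_pairs)) {
    collinear_pairs <- data.frame(i = integer(), j = integer(), r = numeric())
  }
  collinear_pairs <- as.data.frame(collinear_pairs)
  if (nrow(collinear_pairs)) {
    stopifnot(all(c("i", "j", "r") %in% names(collinear_pairs)),
              all(abs(collinear_pairs$r) < 1),
              all(collinear_pairs$i != collinear_pairs$j))
    for (k in seq_len(nrow(collinear_pairs))) {
      ei <- key_effects$effect[match(collinear_pairs$i[k], key_effects$index)]
      ej <- key_effects$effect[match(collinear_pairs$j[k], key_effects$index)]
      if (!is.na(ei) && !is.na(ej) &&
          sign(ei) * sign(ej) * sign(collinear_pairs$r[k]) < 0) {
        stop("config error: collinear pair (", collinear_pairs$i[k], ", ",
             collinear_pairs$j[k], ") has planted effects whose directions ",
             "contradict the target correlation", call. = FALSE)
      }
    }
  }
  structure(
    list(n_per_group_per_set = as.integer(n_per_group_per_set),
         n_metabolites_pos = as.integer(n_metabolites_pos),
         n_metabolites_neg = as.integer(n_metabolites_neg),
         key_effects = key_effects, collinear_pairs = collinear_pairs,
         base_log_mean = base_log_mean, base_log_sd = base_log_sd,
         covariate_effects = covariate_effects, male_prob = male_prob,
         heavy_tails = heavy_tails, seed = as.integer(seed)),
    class = "sim_config"
  )
}

default_subclasses <- function(n_pos, n_neg) {
  pos_pool <- c(rep("acylcarnitine", 30), rep("amino acid", 25),
                rep("lysophosphatidylcholine", 20))
  pos <- rep("other", n_pos)
  pos[seq_len(min(n_pos, length(pos_pool)))] <-
    pos_pool[seq_len(min(n_pos, length(pos_pool)))]
  neg_pool <- c(rep("unsaturated fatty acid", 20),
                rep("saturated fatty acid", 15), rep("C24 bile acid", 15))
  neg <- rep("other", n_neg)
  neg[seq_len(min(n_neg, length(neg_pool)))] <-
    neg_pool[seq_len(min(n_neg, length(neg_pool)))]
  c(pos, neg)
}

#' Simulate a two-phase case/control metabolomics cohort
#'
#' Draws log-normal relative intensities for
#' `4 * n_per_group_per_set` samples (two groups x two sets), plants the
#' configured differential metabolites as mean shifts on the log scale in
#' the dyslipidemia group, induces the configured collinear pairs via a
#' shared latent factor, and draws clinical covariates with the configured
#' group shifts. Fully reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list `(features, meta)`: a [feature_table()] and matching
#'   [cohort_metadata()].
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n1 <- config$n_per_group_per_set
  n <- 4L * n1
  m_pos <- config$n_metabolites_pos
  m_neg <- config$n_metabolites_neg
  m <- m_pos + m_neg
  # sample layout: discovery healthy, discovery dys, replication healthy,
  # replication dys -- deterministic, so round-robin CV folds stay stratified
  set <- rep(c("discovery", "replication"), each = 2L * n1)
  group <- rep(rep(c("healthy", "dyslipidemia"), each = n1), times = 2L)
  y <- as.integer(group == "dyslipidemia")
  sample_ids <- sprintf("S%03d", seq_len(n))
  metabolite_ids <- c(sprintf("P%03d", seq_len(m_pos)),
                      sprintf("N%03d", seq_len(m_neg)))
  mode <- rep(c("positive", "negative"), times = c(m_pos, m_neg))

  draw <- function(n) {
    if (config$heavy_tails) stats::rt(n, df = 5) / sqrt(5 / 3)
    else stats::rnorm(n)
  }
  z <- matrix(draw(n * m), n, m)
  cp <- config$collinear_pairs
  for (k in seq_len(nrow(cp))) {
    r <- cp$r[k]
    a <- sqrt(1 / abs(r) - 1)           # shared latent + independent noise
    latent <- draw(n)
    z[, cp$i[k]] <- (latent + a * draw(n)) / sqrt(1 + a^2)
    z[, cp$j[k]] <- sign(r) * (latent + a * draw(n)) / sqrt(1 + a^2)
  }
  logx <- config$base_log_mean + config$base_log_sd * z
  ke <- config$key_effects
  for (k in seq_len(nrow(ke))) {
    logx[, ke$index[k]] <-
      logx[, ke$index[k]] + ke$effect[k] * config$base_log_sd * y
  }
  features <- feature_table(exp(logx), sample_ids = sample_ids,
                            metabolite_ids = metabolite_ids, mode = mode,
                            subclass = default_subclasses(m_pos, m_neg))

  ce <- config$covariate_effects
  covs <- lapply(seq_len(nrow(ce)), function(i) {
    pmax(ce$mean_healthy[i] + ce$delta[i] * y + ce$sd[i] * stats::rnorm(n),
         0)
  })
  names(covs) <- ce$name
  sex <- ifelse(stats::runif(n) < config$male_prob[y + 1L], "male", "female")
  meta <- cohort_metadata(data.frame(sample_id = sample_ids, group = group,
                                     set = set, sex = sex, covs,
                                     stringsAsFactors = FALSE))
  list(features = features, meta = meta)
}

#' Canonical paper-like synthetic scenario
#'
#' A fixture mirroring the structure of the dyslipidemia study: 2 sets x 2
#' groups x 50 samples, 128 positive-mode + 69 negative-mode metabolites, 12
#' moderately differential metabolites of which two (one per ionization
#' mode, both disease-elevated, effect 2 SD on the log scale) carry the
#' largest effects and play the role of the key metabolites, one
#' disease-decreased collinear pair (target r = 0.97) among the
#' differentials, and clinical covariates with the default group shifts.
#'
#' @param seed integer RNG seed.
#' @return A list `(features, meta, truth)`; `truth` records the planted
#'   key metabolite IDs, all differential IDs and the collinear pair.
#' @export
make_paper_like_scenario <- function(seed = 1L) {
  m_pos <- 128L
  # combined indexing: positive block first, then negative block
  neg <- function(i) m_pos + i
  effects <- data.frame(
    index  = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 10L,
               neg(1L), neg(2L), neg(3L), neg(10L)),
    effect = c(-1.2, -1.2, -0.9, -0.9, -1.0, -0.8, 0.9, 2.0,
               -0.9, 0.9, 1.0, 2.0)
  )
  cfg <- sim_config(
    n_per_group_per_set = 50L,
    key_effects = effects,
    collinear_pairs = data.frame(i = 1L, j = 2L, r = 0.97),
    seed = seed
  )
  sim <- simulate_cohort(cfg)
  ids <- sim$features$metabolite_ids
  sim$truth <- list(
    keys = ids[c(10L, neg(10L))],
    differential = ids[effects$index],
    collinear_pair = ids[c(1L, 2L)],
    config = cfg
  )
  sim
}
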
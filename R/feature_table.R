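#' Construct a metabolomics feature table
#'
#' A feature table holds relative peak intensities for a set of samples
#' (rows) and named metabolites (columns), together with a per-metabolite
#' ionization-mode tag (`positive`/`negative`) and a free-text subclass
#' annotation (e.g. "acylcarnitine", "unsaturated fatty acid").
#'
#' Raw intensities must be non-negative; a table that has been
#' log-transformed (see [log_transform()]) carries a `transform` record and
#' is exempt from the non-negativity check.
#'
#' @param intensities numeric matrix, samples x metabolites. Row and column
#'   names, when present, must agree with `sample_ids` / `metabolite_ids`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param metabolite_ids character vector of unique metabolite identifiers.
#' @param mode character vector, one of `"positive"`/`"negative"` per
#'   metabolite. A single value is recycled.
#' @param subclass character vector of per-metabolite subclass annotations.
#'   A single value is recycled; `NA` is mapped to `"other"`.
#' @param transform internal: `NULL` for raw intensities, or a list with
#'   elements `base` and `pseudocount` describing an applied log transform.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, sample_ids = rownames(intensities),
                          metabolite_ids = colnames(intensities),
                          mode = "positive", subclass = "other",
                          transform = NULL) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities)) {
    stop("validation error: intensities must be numeric", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_len(nrow(intensities)))
  }
  if (is.null(metabolite_ids)) {
    metabolite_ids <- sprintf("M%03d", seq_len(ncol(intensities)))
  }
  sample_ids <- as.character(sample_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (length(sample_ids) != nrow(intensities)) {
    stop("validation error: sample_ids length != number of rows", call. = FALSE)
  }
  if (length(metabolite_ids) != ncol(intensities)) {
    stop("validation error: metabolite_ids length != number of columns",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("validation error: duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metabolite_ids)) {
    stop("validation error: duplicate metabolite IDs: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]),
               collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    bad <- which(!is.finite(intensities), arr.ind = TRUE)[1, ]
    stop("validation error: non-finite intensity at sample '",
         sample_ids[bad[1]], "', metabolite '", metabolite_ids[bad[2]], "'",
         call. = FALSE)
  }
  if (is.null(transform) && any(intensities < 0)) {
    bad <- which(intensities < 0, arr.ind = TRUE)[1, ]
    stop("validation error: negative intensity at sample '",
         sample_ids[bad[1]], "', metabolite '", metabolite_ids[bad[2]], "'",
         call. = FALSE)
  }
  mode <- rep_len(as.character(mode), length(metabolite_ids))
  if (!all(mode %in% c("positive", "negative"))) {
    stop("validation error: mode must be 'positive' or 'negative'",
         call. = FALSE)
  }
  subclass <- rep_len(as.character(subclass), length(metabolite_ids))
  subclass[is.na(subclass)] <- "other"
  dimnames(intensities) <- list(sample_ids, metabolite_ids)
  structure(
    list(intensities = intensities, sample_ids = sample_ids,
         metabolite_ids = metabolite_ids, mode = mode, subclass = subclass,
         transform = transform),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", length(x$sample_ids), " samples x ",
      length(x$metabolite_ids), " metabolites (",
      sum(x$mode == "positive"), " positive / ",
      sum(x$mode == "negative"), " negative mode)\n", sep = "")
  if (!is.null(x$transform)) {
    cat("  log-transformed: base ", format(x$transform$base),
        ", pseudocount ", format(x$transform$pseudocount), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table by samples and/or metabolites
#'
#' @param x a [feature_table()].
#' @param samples sample IDs or indices to keep (default all).
#' @param metabolites metabolite IDs or indices to keep (default all).
#' @return A `feature_table` restricted to the requested rows/columns.
#' @export
subset_feature_table <- function(x, samples = NULL, metabolites = NULL) {
  stopifnot(inherits(x, "feature_table"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  mi <- if (is.null(metabolites)) seq_along(x$metabolite_ids) else metabolites
  if (is.character(si)) si <- match(si, x$sample_ids)
  if (is.character(mi)) mi <- match(mi, x$metabolite_ids)
  if (anyNA(si)) stop("unknown sample ID in subset", call. = FALSE)
  if (anyNA(mi)) stop("unknown metabolite ID in subset", call. = FALSE)
  feature_table(x$intensities[si, mi, drop = FALSE],
                sample_ids = x$sample_ids[si],
                metabolite_ids = x$metabolite_ids[mi],
                mode = x$mode[mi], subclass = x$subclass[mi],
                transform = x$transform)
}

#' Construct per-sample cohort metadata
#'
#' Holds the group label (`healthy`/`dyslipidemia`), the set assignment
#' (`discovery`/`replication`) and any clinical covariates (age, sex, BMI,
#' lipid profile, ...). Group is coded healthy = 0, dyslipidemia = 1 for all
#' regressions, so a positive coefficient means disease-elevated.
#'
#' @param df data frame with columns `sample_id`, `group`, `set` plus
#'   covariates. `group` must be `healthy`/`dyslipidemia` (or 0/1); `set`
#'   must be `discovery`/`replication`.
#' @return A `cohort_metadata` data frame.
#' @export
cohort_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "set")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("validation error: metadata missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("validation error: duplicate sample IDs in metadata", call. = FALSE)
  }
  if (is.numeric(df$group)) {
    df$group <- c("healthy", "dyslipidemia")[df$group + 1L]
  }
  df$group <- as.character(df$group)
  df$set <- as.character(df$set)
  if (anyNA(df$group) || !all(df$group %in% c("healthy", "dyslipidemia"))) {
    stop("validation error: group must be 'healthy' or 'dyslipidemia', no NA",
         call. = FALSE)
  }
  if (anyNA(df$set) || !all(df$set %in% c("discovery", "replication"))) {
    stop("validation error: set must be 'discovery' or 'replication', no NA",
         call. = FALSE)
  }
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Numeric 0/1 disease coding of the group label
#'
#' @param meta a [cohort_metadata()] data frame (or a character vector of
#'   group labels).
#' @return Integer vector: healthy = 0, dyslipidemia = 1.
#' @export
group_code <- function(meta) {
  g <- if (is.data.frame(meta)) meta$group else as.character(meta)
  as.integer(g == "dyslipidemia")
}

check_joint <- function(table, meta) {
  stopifnot(inherits(table, "feature_table"))
  if (!inherits(meta, "cohort_metadata")) meta <- cohort_metadata(meta)
  if (!identical(table$sample_ids, meta$sample_id)) {
    if (setequal(table$sample_ids, meta$sample_id)) {
      meta <- meta[match(table$sample_ids, meta$sample_id), , drop = FALSE]
      rownames(meta) <- NULL
      class(meta) <- c("cohort_metadata", "data.frame")
    } else {
      stop("validation error: sample IDs of feature table and metadata differ",
           call. = FALSE)
    }
  }
  meta
}

#' Read a feature table from delimited text
#'
#' Expects a header row of metabolite IDs and a first column of sample IDs.
#' Mode and subclass annotations come from a companion annotation file
#' (columns `metabolite_id`, `mode`, `subclass`); without one, every
#' metabolite is tagged positive mode, subclass "other".
#'
#' @param path path to the intensity CSV/TSV.
#' @param annotation optional path to an annotation CSV/TSV, or a data frame.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, annotation = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  metabolite_ids <- colnames(mat)
  mode <- "positive"; subclass <- "other"
  if (!is.null(annotation)) {
    ann <- if (is.data.frame(annotation)) annotation else {
      utils::read.table(annotation, header = TRUE, sep = sep,
                        stringsAsFactors = FALSE)
    }
    idx <- match(metabolite_ids, as.character(ann$metabolite_id))
    if (anyNA(idx)) {
      stop("validation error: annotation missing metabolite(s): ",
           paste(metabolite_ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    mode <- as.character(ann$mode)[idx]
    subclass <- if ("subclass" %in% names(ann)) {
      as.character(ann$subclass)[idx]
    } else "other"
  }
  feature_table(mat, sample_ids = sample_ids, metabolite_ids = metabolite_ids,
                mode = mode, subclass = subclass)
}

#' Write a feature table (and its annotation) to delimited text
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces the matrix to within floating-point formatting error.
#'
#' @param table a [feature_table()].
#' @param path output path for the intensity table.
#' @param annotation_path optional output path for the annotation table.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, annotation_path = NULL,
                                sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  vals <- format(table$intensities, digits = 17, trim = TRUE,
                 scientific = FALSE)
  df <- data.frame(sample_id = table$sample_ids, vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", table$metabolite_ids)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(annotation_path)) {
    ann <- data.frame(metabolite_id = table$metabolite_ids,
                      mode = table$mode, subclass = table$subclass,
                      stringsAsFactors = FALSE)
    utils::write.table(ann, annotation_path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read cohort metadata from delimited text
#'
#' @param path path to the metadata CSV/TSV (columns `sample_id`, `group`,
#'   `set`, covariates).
#' @param sep field delimiter.
#' @return A [cohort_metadata()] data frame.
#' @export
read_cohort_metadata <- function(path, sep = ",") {
  cohort_metadata(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE))
}

#' Write cohort metadata to delimited text
#'
#' @param meta a [cohort_metadata()] data frame.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort_metadata <- function(meta, path, sep = ",") {
  utils::write.table(as.data.frame(meta), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log-transform a feature table
#'
#' Replaces each intensity x by log_base(x + pseudocount), leaving all
#' annotations untouched. A strictly positive pseudocount is required when
#' the table contains zeros.
#'
#' @param table a [feature_table()] of raw intensities.
#' @param base logarithm base: 2 (default; fold changes read as log2),
#'   `exp(1)`, or 10.
#' @param pseudocount non-negative offset added before taking logs.
#' @return A `feature_table` of log intensities, with a `transform` record.
#' @export
log_transform <- function(table, base = 2, pseudocount = 0) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.null(table$transform)) {
    stop("table is already log-transformed", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative", call. = FALSE)
  if (pseudocount == 0 && any(table$intensities == 0)) {
    stop("zero intensities present: a positive pseudocount is required",
         call. = FALSE)
  }
  feature_table(log(table$intensities + pseudocount, base = base),
                sample_ids = table$sample_ids,
                metabolite_ids = table$metabolite_ids,
                mode = table$mode, subclass = table$subclass,
                transform = list(base = base, pseudocount = pseudocount))
}

#' Split a cohort into its discovery and replication halves
#'
#' Partitions samples by the metadata `set` column. The two halves are
#' disjoint and together exhaust the cohort.
#'
#' @param table a [feature_table()].
#' @param meta matching [cohort_metadata()].
#' @return A list with elements `discovery` and `replication`, each a list
#'   `(features, meta)`.
#' @export
split_sets <- function(table, meta) {
  meta <- check_joint(table, meta)
  out <- lapply(c(discovery = "discovery", replication = "replication"),
                function(s) {
    keep <- which(meta$set == s)
    if (!length(keep)) {
      stop("split error: no samples in the '", s, "' set", call. = FALSE)
    }
    m <- meta[keep, , drop = FALSE]
    rownames(m) <- NULL
    class(m) <- c("cohort_metadata", "data.frame")
    list(features = subset_feature_table(table, samples = keep), meta = m)
  })
  out
}
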
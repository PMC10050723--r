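#' Feature filters
#'
#' The preprocessing stage mirrors standard methylation-array QC plus a
#' per-feature differential filter applied to all three omics layers:
#'
#' * [filter_missing()] removes probes whose missing fraction exceeds a
#'   threshold (strictly more than; the boundary is kept) and mean-imputes the
#'   surviving missing entries per feature.
#' * [filter_iqr()] keeps features whose interquartile range is strictly
#'   greater than a floor, dropping near-constant probes.
#' * [filter_exclusion()] removes user-supplied blocklists (sex-chromosome,
#'   SNP, cross-reactive probes and the like).
#' * [filter_ttest()] keeps features whose two-class Welch t-test has
#'   `p < p_max`.
#'
#' Each filter returns the filtered matrix together with a one-row report
#' tibble recording the stage, the in/out feature counts and the removed IDs,
#' so a full run can account exactly for every dropped feature.
#'
#' @param matrix an [omics_matrix()].
#' @param max_missing_fraction features with missing fraction strictly greater
#'   than this are removed; in `[0, 1)`.
#' @return a list with elements `matrix` and `report`.
#' @name preprocess
NULL

filter_report <- function(stage, removed_ids, features_in, extra = list()) {
  tibble::tibble(
    stage = stage,
    features_in = as.integer(features_in),
    features_out = as.integer(features_in - length(removed_ids)),
    n_removed = length(removed_ids),
    removed_ids = list(removed_ids),
    !!!extra
  )
}

#' @rdname preprocess
#' @export
filter_missing <- function(matrix, max_missing_fraction = 0.2) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction < 1)
  frac <- rowMeans(is.na(matrix))
  keep <- frac <= max_missing_fraction
  out <- unclass(matrix)[keep, , drop = FALSE]
  if (anyNA(out)) {
    mu <- rowMeans(out, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- mu[idx[, 1]]
  }
  list(matrix = om_like(out, matrix),
       report = filter_report("missing_fraction", rownames(matrix)[!keep], nrow(matrix),
                              extra = list(n_imputed = sum(is.na(unclass(matrix)[keep, ])))))
}

#' @rdname preprocess
#' @param min_iqr features with IQR (75th minus 25th percentile,
#'   linear-interpolation quantiles) at or below this are removed.
#' @export
filter_iqr <- function(matrix, min_iqr = 0.1) {
  stopifnot(!anyNA(matrix))
  iqr <- apply(unclass(matrix), 1L, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    q[2] - q[1]
  })
  keep <- iqr > min_iqr
  list(matrix = om_features(matrix, which(keep)),
       report = filter_report("iqr", rownames(matrix)[!keep], nrow(matrix)))
}

#' @rdname preprocess
#' @param blocklists a character vector or list of character vectors of feature
#'   IDs to remove; IDs absent from the matrix are ignored but counted.
#' @export
filter_exclusion <- function(matrix, blocklists) {
  block <- unique(unlist(blocklists, use.names = FALSE))
  removed <- intersect(rownames(matrix), block)
  n_unknown <- length(setdiff(block, rownames(matrix)))
  if (n_unknown > 0) {
    message(sprintf("filter_exclusion: %d blocklist IDs not present in the matrix.",
                    n_unknown))
  }
  keep <- setdiff(rownames(matrix), removed)
  list(matrix = om_features(matrix, keep),
       report = filter_report("exclusion", removed, nrow(matrix),
                              extra = list(n_unknown_ids = n_unknown)))
}

#' Per-feature two-class t-test
#'
#' Vectorised Welch (default) or pooled-variance two-sample t-test of every
#' feature against the two-class labels. Features that are constant within
#' both classes and have equal class means carry no information; their p-value
#' is reported as 1. Constant features with distinct class means separate the
#' classes perfectly and get p = 0.
#'
#' @param matrix an [omics_matrix()] with no missing values.
#' @param labels tibble with columns `sample_id`, `label` covering the
#'   matrix's samples.
#' @param var_equal use the pooled-variance statistic instead of Welch.
#' @return a tibble with columns `feature_id`, `statistic`, `df`, `p_value`.
#' @export
feature_t_test <- function(matrix, labels, var_equal = FALSE) {
  stopifnot(!anyNA(matrix))
  validate_labels(labels)
  grp <- labels$label[match(colnames(matrix), labels$sample_id)]
  if (anyNA(grp)) rlang::abort("Every matrix sample needs a label.")
  lv <- sort(unique(grp), method = "radix")
  x <- unclass(matrix)[, grp == lv[1], drop = FALSE]
  y <- unclass(matrix)[, grp == lv[2], drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) rlang::abort("Need at least 2 samples per class.")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(matrix))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(stat), df)
  degenerate <- se == 0
  equal_means <- degenerate & (m1 == m2)
  p[degenerate] <- 0          # perfect separation at zero within-class spread
  p[equal_means] <- 1         # no variation, no difference: uninformative
  stat[equal_means] <- 0
  tibble::tibble(feature_id = rownames(matrix), statistic = unname(stat),
                 df = unname(df), p_value = unname(p))
}

#' @rdname preprocess
#' @param labels tibble with columns `sample_id`, `label`.
#' @param p_max retain features with two-sided `p < p_max` (strict).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @export
filter_ttest <- function(matrix, labels, p_max = 0.05, var_equal = FALSE) {
  tt <- feature_t_test(matrix, labels, var_equal = var_equal)
  keep <- tt$p_value < p_max
  list(matrix = om_features(matrix, which(keep)),
       report = filter_report("ttest", rownames(matrix)[!keep], nrow(matrix)))
}

#' Read a feature exclusion list
#'
#' One feature ID per line; blank lines and lines starting with `#` are
#' skipped.
#'
#' @param path file path.
#' @return character vector of IDs.
#' @export
read_exclusion_list <- function(path) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids) & !startsWith(ids, "#")]
}

#' Standard CpG preprocessing
#'
#' Applies, in order: missing-fraction filter with mean imputation, IQR
#' filter, exclusion-list removal.
#'
#' @param cpg CpG [omics_matrix()].
#' @param config a [trimint_config()].
#' @param blocklists optional list of excluded-ID character vectors.
#' @return list with `matrix` and a `reports` tibble (one row per stage).
#' @export
preprocess_cpg <- function(cpg, config = trimint_config(), blocklists = list()) {
  s1 <- filter_missing(cpg, config$max_missing_fraction)
  s2 <- filter_iqr(s1$matrix, config$min_iqr)
  s3 <- filter_exclusion(s2$matrix, blocklists)
  list(matrix = s3$matrix,
       reports = dplyr::bind_rows(s1$report, s2$report, s3$report))
}
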
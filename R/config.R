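#' Pipeline run configuration
#'
#' Collects every tunable of the grouping-scoring-modeling pipeline with the
#' recommended defaults: pair correlation threshold `alpha = 0.6`, group
#' threshold `beta = alpha`, correlation and t-test p-value gates at 0.05,
#' 100 outer Monte Carlo splits holding out 10% of samples, cumulative models
#' over the 10 best-scoring groups, and a group-frequency floor of 5 for the
#' significance tables.
#'
#' @param alpha pair correlation threshold in (0, 1]; a miRNA-CpG pair is kept
#'   when `|r| > alpha` (strict).
#' @param beta group correlation threshold in (0, 1]; a gene joins a group when
#'   its correlation with both pair members exceeds `beta`.
#' @param pair_p_max two-sided p-value gate for pair correlations; `1` disables.
#' @param ttest_p_max per-feature Welch t-test gate; features with `p < ttest_p_max`
#'   are retained; `1` disables (degenerate features still drop).
#' @param n_outer_splits number of outer Monte Carlo train/test splits.
#' @param test_fraction fraction of samples held out per outer split.
#' @param inner_cv_iterations Monte Carlo iterations of the inner group-scoring CV.
#' @param inner_test_fraction held-out fraction of the inner CV.
#' @param top_k_groups number of best-scoring groups used for cumulative models.
#' @param min_group_frequency groups seen in `<= min_group_frequency` splits are
#'   excluded from the significance tables.
#' @param rf_trees number of trees per random forest.
#' @param score_metric_weights named numeric vector of metric weights used as the
#'   group score; names among `accuracy`, `auc`, `sensitivity`, `specificity`.
#' @param seed master seed; every split derives its own stream from it.
#' @param leakage_mode `"global"` computes the t-test filter, pairs and groups
#'   on all samples (mirroring the published order of operations);
#'   `"train_only"` restricts them to each split's training samples, which is
#'   statistically safer and is the recommended setting for unbiased test
#'   metrics.
#' @param use_abs_beta use `|r| > beta` in grouping (default) rather than the
#'   signed `r > beta`.
#' @param count_top_k_only if `TRUE`, group/feature frequencies count only
#'   appearances within each split's top `top_k_groups`.
#' @param max_missing_fraction CpG probes with a greater missing fraction are
#'   removed during preprocessing.
#' @param min_iqr CpG probes with interquartile range `<= min_iqr` are removed.
#' @param positive_label class treated as positive for sensitivity/AUC; default
#'   is the lexicographically first label observed.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return a `trimint_config` list.
#' @examples
#' cfg <- trimint_config(n_outer_splits = 10, seed = 7)
#' cfg$alpha
#' @export
trimint_config <- function(alpha = 0.6,
                           beta = alpha,
                           pair_p_max = 0.05,
                           ttest_p_max = 0.05,
                           n_outer_splits = 100,
                           test_fraction = 0.1,
                           inner_cv_iterations = 5,
                           inner_test_fraction = 0.1,
                           top_k_groups = 10,
                           min_group_frequency = 5,
                           rf_trees = 100,
                           score_metric_weights = c(accuracy = 1),
                           seed = 1,
                           leakage_mode = c("global", "train_only"),
                           use_abs_beta = TRUE,
                           count_top_k_only = FALSE,
                           max_missing_fraction = 0.2,
                           min_iqr = 0.1,
                           positive_label = NULL,
                           var_equal = FALSE) {
  leakage_mode <- match.arg(leakage_mode)
  stopifnot(
    alpha > 0, alpha <= 1, beta > 0, beta <= 1,
    pair_p_max > 0, pair_p_max <= 1, ttest_p_max > 0, ttest_p_max <= 1,
    n_outer_splits >= 1, test_fraction > 0, test_fraction < 1,
    inner_cv_iterations >= 1, inner_test_fraction > 0, inner_test_fraction < 1,
    top_k_groups >= 1, min_group_frequency >= 0, rf_trees >= 1,
    max_missing_fraction >= 0, max_missing_fraction < 1,
    is.numeric(score_metric_weights), length(score_metric_weights) >= 1
  )
  known <- c("accuracy", "auc", "sensitivity", "specificity")
  if (is.null(names(score_metric_weights)) ||
      !all(names(score_metric_weights) %in% known)) {
    rlang::abort(paste0("score_metric_weights must be named among: ",
                        paste(known, collapse = ", ")))
  }
  if (any(score_metric_weights < 0) || sum(score_metric_weights) <= 0) {
    rlang::abort("score_metric_weights must be non-negative with positive sum.")
  }
  structure(list(
    alpha = alpha, beta = beta,
    pair_p_max = pair_p_max, ttest_p_max = ttest_p_max,
    n_outer_splits = as.integer(n_outer_splits),
    test_fraction = test_fraction,
    inner_cv_iterations = as.integer(inner_cv_iterations),
    inner_test_fraction = inner_test_fraction,
    top_k_groups = as.integer(top_k_groups),
    min_group_frequency = as.integer(min_group_frequency),
    rf_trees = as.integer(rf_trees),
    score_metric_weights = score_metric_weights / sum(score_metric_weights),
    seed = as.integer(seed),
    leakage_mode = leakage_mode,
    use_abs_beta = isTRUE(use_abs_beta),
    count_top_k_only = isTRUE(count_top_k_only),
    max_missing_fraction = max_missing_fraction,
    min_iqr = min_iqr,
    positive_label = positive_label,
    var_equal = isTRUE(var_equal)
  ), class = "trimint_config")
}

#' @export
print.trimint_config <- function(x, ...) {
  cat("<trimint_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) v <- "<first label>"
    if (!is.null(names(v)) && length(names(v)) > 0 && any(nzchar(names(v)))) {
      v <- paste(names(v), v, sep = "=", collapse = ", ")
    }
    cat(sprintf("  %-22s %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}

# All randomness flows from the master seed. Split i uses seed + i; nested
# streams (inner CV, per-group forests, per-k models) hash further with a
# small prime, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + as.double(i)) %% 2147483647)
}

nested_seed <- function(seed, i) {
  as.integer((as.double(seed) * 10007 + as.double(i)) %% 2147483647)
}
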
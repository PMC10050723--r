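#' Union of gene sets over the top-k groups
#'
#' Genes of the groups ranked 1..k, in first-appearance order with duplicates
#' removed — the feature set of cumulative model number k.
#'
#' @param scored tibble from [score_groups()] (sorted by rank, with a `genes`
#'   list-column).
#' @param k number of top groups to merge, `1 <= k <= nrow(scored)`.
#' @return character vector of gene IDs.
#' @export
cumulative_union <- function(scored, k) {
  stopifnot(k >= 1, k <= nrow(scored))
  ord <- scored[order(scored$rank), ]
  unique(unlist(ord$genes[seq_len(k)], use.names = FALSE))
}

#' Binary classification metrics
#'
#' Accuracy, sensitivity and specificity from the confusion matrix with
#' respect to `positive_label`, plus the Mann-Whitney AUC computed from the
#' positive-class scores (tied scores count one half). When the truth
#' contains a single class, AUC is undefined and reported as `NA`; the other
#' metrics are still computed (a sensitivity or specificity with an empty
#' denominator is likewise `NA`).
#'
#' @param true_labels,predicted_labels character/factor vectors of equal length.
#' @param positive_scores numeric positive-class scores, or `NULL` to skip AUC.
#' @param positive_label the class counted as positive.
#' @return a one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `auc`.
#' @examples
#' compute_metrics(c("a", "a", "b"), c("a", "b", "b"), c(0.9, 0.4, 0.2), "a")
#' @export
compute_metrics <- function(true_labels, predicted_labels,
                            positive_scores = NULL, positive_label) {
  stopifnot(length(true_labels) == length(predicted_labels),
            length(true_labels) >= 1)
  truth_pos <- true_labels == positive_label
  pred_pos <- predicted_labels == positive_label
  tp <- sum(truth_pos & pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  tibble::tibble(
    accuracy = (tp + tn) / length(true_labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = if (is.null(positive_scores)) NA_real_ else
      mann_whitney_auc(positive_scores, truth_pos)
  )
}

#' Mann-Whitney AUC
#'
#' Rank-statistic area under the ROC curve: the probability that a random
#' positive outscores a random negative, ties counting one half. Invariant
#' under any strictly monotone transform of the scores.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param is_positive logical vector of the same length.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
mann_whitney_auc <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate cumulative top-k models on held-out samples
#'
#' The modeling (M) stage. For each k up to `top_k_groups` (or the number of
#' available groups, whichever is smaller), a fresh classifier is fitted on
#' the training samples restricted to [cumulative_union()] of the k
#' best-scoring groups and evaluated on the held-out test samples. One row of
#' the performance table is emitted per k.
#'
#' @param scored tibble from [score_groups()].
#' @param mrna_train,mrna_test mRNA [omics_matrix()] restricted to disjoint
#'   train/test sample sets.
#' @param labels label tibble covering both sample sets.
#' @param config a [trimint_config()].
#' @param seed integer stream for the per-k forests.
#' @return a tibble with columns `cumulative_rank`, `unique_gene_count`,
#'   `accuracy`, `specificity`, `sensitivity`, `auc`.
#' @export
evaluate_cumulative <- function(scored, mrna_train, mrna_test, labels,
                                config = trimint_config(), seed = config$seed) {
  stopifnot(nrow(scored) >= 1)
  stopifnot(length(intersect(colnames(mrna_train), colnames(mrna_test))) == 0)
  mrna_train <- om_samples(mrna_train,
                           sort(colnames(mrna_train), method = "radix"))
  mrna_test <- om_samples(mrna_test, sort(colnames(mrna_test), method = "radix"))
  y_train <- classify_factor(labels, colnames(mrna_train), config)
  y_test <- classify_factor(labels, colnames(mrna_test), config)
  positive <- levels(y_train)[2]
  xs_train <- t(unclass(mrna_train))
  xs_test <- t(unclass(mrna_test))
  spec <- classifier_spec(n_trees = config$rf_trees)
  purrr::map_dfr(seq_len(min(config$top_k_groups, nrow(scored))), function(k) {
    genes <- cumulative_union(scored, k)
    fit <- fit_classifier(spec, xs_train[, genes, drop = FALSE], y_train,
                          seed = nested_seed(seed, 500000L + k))
    pr <- predict_classifier(fit, xs_test[, genes, drop = FALSE], positive)
    m <- compute_metrics(as.character(y_test), pr$labels, pr$score, positive)
    tibble::tibble(cumulative_rank = k, unique_gene_count = length(genes),
                   accuracy = m$accuracy, specificity = m$specificity,
                   sensitivity = m$sensitivity, auc = m$auc)
  })
}
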
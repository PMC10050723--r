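#' Classifier specification
#'
#' The scoring and modeling stages use a pluggable classifier behind a tiny
#' fit/predict interface; the shipped family is the random forest (via
#' \pkg{ranger}, grown as a probability forest so a positive-class score is
#' always available). `n_candidate_vars` defaults to the square root of the
#' feature count at fit time.
#'
#' @param kind classifier family; `"random_forest"` is the implemented one.
#' @param n_trees number of trees.
#' @param n_candidate_vars candidate features per node split, `NULL` for sqrt.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = "random_forest", n_trees = 100,
                            n_candidate_vars = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 n_candidate_vars = n_candidate_vars),
            class = "classifier_spec")
}

# x: samples x features numeric matrix; y: factor with 2 levels.
fit_classifier <- function(spec, x, y, seed) {
  stopifnot(inherits(spec, "classifier_spec"))
  df <- as.data.frame(x)
  df$.class <- y
  ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = spec$n_trees,
    mtry = spec$n_candidate_vars %||% max(1L, floor(sqrt(ncol(x)))),
    probability = TRUE, seed = seed, num.threads = 1,
    verbose = FALSE
  )
}

# Returns list(labels = predicted class labels, score = positive-class prob).
predict_classifier <- function(fit, x, positive_label) {
  prob <- stats::predict(fit, data = as.data.frame(x), num.threads = 1,
                         verbose = FALSE)$predictions
  pos <- prob[, positive_label]
  lv <- colnames(prob)
  neg <- setdiff(lv, positive_label)
  list(labels = ifelse(pos >= 0.5, positive_label, neg), score = unname(pos))
}

# Stratified Monte Carlo split: per class, round(frac * n) test samples
# (at least 1, at most n - 1 so the class survives in training). Candidates
# are visited in sample-ID order, so the drawn sample *set* depends only on
# the IDs, the labels and the seed — never on input column order.
stratified_split <- function(y, test_fraction, seed, ids = NULL) {
  ids <- ids %||% as.character(seq_along(y))
  ord <- order(ids, method = "radix")
  idx_by_class <- split(ord, y[ord])
  withr::with_seed(seed, {
    test <- unlist(lapply(idx_by_class, function(idx) {
      n_test <- min(length(idx) - 1L, max(1L, round(test_fraction * length(idx))))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

# Inner CV partitions, shared across all groups of one outer split so group
# scores are computed on identical folds and are directly comparable.
make_inner_splits <- function(y, iterations, test_fraction, seed, ids = NULL) {
  lapply(seq_len(iterations), function(i) {
    attempt_seed <- nested_seed(seed, i)
    for (attempt in 1:10) {
      sp <- stratified_split(y, test_fraction, attempt_seed, ids)
      if (length(unique(y[sp$train])) == 2 && length(unique(y[sp$test])) == 2) {
        return(sp)
      }
      attempt_seed <- nested_seed(attempt_seed, 97L + attempt)
    }
    rlang::abort("Could not draw a stratified inner split keeping both classes.")
  })
}

weighted_metric_score <- function(metrics, weights) {
  vals <- vapply(names(weights), function(nm) metrics[[nm]], numeric(1))
  if (anyNA(vals)) vals[is.na(vals)] <- 0
  sum(vals * weights)
}

#' Score groups by cross-validated classification and rank them
#'
#' The scoring (S) stage. Each group's gene-expression submatrix (training
#' samples only) is evaluated by stratified Monte Carlo cross-validation: in
#' every inner iteration a classifier is fitted on the inner-training part
#' and the configured weighted metric combination (default: accuracy) is
#' computed on the inner-test part; the group score is the mean over
#' iterations. The inner partitions are drawn once and reused for every
#' group, so scores are comparable across groups. Groups are then sorted by
#' decreasing score — ties broken toward larger gene sets, then by name —
#' and ranked 1..m.
#'
#' @param groups tibble from [build_groups()].
#' @param mrna_train mRNA [omics_matrix()] restricted to training samples.
#' @param labels label tibble covering the training samples.
#' @param config a [trimint_config()].
#' @param seed integer stream for the inner splits and forests.
#' @return `groups` with added columns `score`, `rank`,
#'   `per_iteration_scores` (list-column), sorted by rank.
#' @export
score_groups <- function(groups, mrna_train, labels, config = trimint_config(),
                         seed = config$seed) {
  if (nrow(groups) == 0) {
    return(dplyr::mutate(groups, score = numeric(0), rank = integer(0),
                         per_iteration_scores = list()))
  }
  mrna_train <- om_samples(mrna_train,
                           sort(colnames(mrna_train), method = "radix"))
  y <- classify_factor(labels, colnames(mrna_train), config)
  positive <- levels(y)[2]
  inner <- make_inner_splits(y, config$inner_cv_iterations,
                             config$inner_test_fraction, seed,
                             ids = colnames(mrna_train))
  xs <- t(unclass(mrna_train))  # samples x features
  spec <- classifier_spec(n_trees = config$rf_trees)
  # forest seed depends on the iteration only: groups with identical gene
  # sets then receive identical scores and ties fall to the deterministic rule
  scores <- purrr::map(groups$genes, function(gene_ids) {
    vapply(seq_along(inner), function(i) {
      sp <- inner[[i]]
      fit <- fit_classifier(spec, xs[sp$train, gene_ids, drop = FALSE],
                            y[sp$train],
                            seed = nested_seed(seed, 900000L + i))
      pr <- predict_classifier(fit, xs[sp$test, gene_ids, drop = FALSE], positive)
      m <- compute_metrics(as.character(y[sp$test]), pr$labels, pr$score, positive)
      weighted_metric_score(m, config$score_metric_weights)
    }, numeric(1))
  })
  out <- dplyr::mutate(groups,
                       per_iteration_scores = scores,
                       score = vapply(scores, mean, numeric(1)))
  out <- dplyr::arrange(out, dplyr::desc(.data$score),
                        dplyr::desc(.data$n_genes), .data$group)
  dplyr::mutate(out, rank = dplyr::row_number())
}

# Two-level factor over the matrix's samples; positive class is the second
# level so predict_classifier scores refer to it.
classify_factor <- function(labels, sample_ids, config) {
  lab <- labels$label[match(sample_ids, labels$sample_id)]
  if (anyNA(lab)) rlang::abort("Every sample needs a label.")
  lv <- sort(unique(labels$label), method = "radix")
  positive <- config$positive_label %||% lv[1]
  if (!positive %in% lv) {
    rlang::abort(sprintf("positive_label '%s' is not one of the classes (%s).",
                         positive, paste(lv, collapse = ", ")))
  }
  factor(lab, levels = c(setdiff(lv, positive), positive))
}
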
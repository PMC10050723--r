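#' Run one outer Monte Carlo split
#'
#' Draws a stratified train/test split of the samples, runs discovery
#' (per-feature t-test filter, miRNA-CpG pairing, gene grouping) on either
#' all samples (`leakage_mode = "global"`) or the training samples only
#' (`"train_only"`), scores and ranks the groups on the training samples, and
#' evaluates the cumulative top-k models on the held-out samples.
#'
#' @param mirna,cpg,mrna sample-aligned, preprocessed [omics_matrix()] objects.
#' @param labels label tibble covering the samples.
#' @param config a [trimint_config()].
#' @param split_index 1-based split number; the split's seed is
#'   `config$seed + split_index`.
#' @param groups optional precomputed group tibble (used internally to avoid
#'   recomputing identical global-mode discovery for every split).
#' @return a `trimint_split` list: `split_index`, `seed`, `scored_groups`,
#'   `performance`, `n_pairs`, `n_groups`, `train_ids`, `test_ids`.
#' @export
run_split <- function(mirna, cpg, mrna, labels, config = trimint_config(),
                      split_index = 1, groups = NULL) {
  seed_i <- derive_seed(config$seed, split_index)
  y <- classify_factor(labels, colnames(mrna), config)
  sp <- stratified_split(y, config$test_fraction, seed_i, ids = colnames(mrna))
  train_ids <- colnames(mrna)[sp$train]
  test_ids <- colnames(mrna)[sp$test]

  n_pairs <- NA_integer_
  if (is.null(groups)) {
    discovery_ids <- if (config$leakage_mode == "train_only") train_ids else colnames(mrna)
    disc <- discover_groups(om_samples(mirna, discovery_ids),
                            om_samples(cpg, discovery_ids),
                            om_samples(mrna, discovery_ids),
                            labels, config)
    groups <- disc$groups
    n_pairs <- disc$n_pairs
  } else {
    n_pairs <- attr(groups, "n_pairs") %||% NA_integer_
  }

  mrna_train <- om_samples(mrna, train_ids)
  mrna_test <- om_samples(mrna, test_ids)
  scored <- score_groups(groups, mrna_train, labels, config, seed = seed_i)
  perf <- if (nrow(scored) > 0) {
    evaluate_cumulative(scored, mrna_train, mrna_test, labels, config,
                        seed = seed_i)
  } else {
    tibble::tibble(cumulative_rank = integer(), unique_gene_count = integer(),
                   accuracy = numeric(), specificity = numeric(),
                   sensitivity = numeric(), auc = numeric())
  }
  structure(list(split_index = as.integer(split_index), seed = seed_i,
                 scored_groups = scored, performance = perf,
                 n_pairs = as.integer(n_pairs), n_groups = nrow(scored),
                 train_ids = train_ids, test_ids = test_ids),
            class = "trimint_split")
}

# Discovery = t-test filter on all three layers, pairing, grouping.
discover_groups <- function(mirna, cpg, mrna, labels, config) {
  a <- filter_ttest(mirna, labels, config$ttest_p_max, config$var_equal)$matrix
  b <- filter_ttest(cpg, labels, config$ttest_p_max, config$var_equal)$matrix
  c_ <- filter_ttest(mrna, labels, config$ttest_p_max, config$var_equal)$matrix
  pairs <- if (nrow(a) > 0 && nrow(b) > 0) {
    suppressWarnings(detect_pairs(a, b, config$alpha, config$pair_p_max))
  } else {
    detect_pairs(a[0, , drop = FALSE], b, config$alpha, config$pair_p_max)
  }
  groups <- if (nrow(pairs) > 0 && nrow(c_) > 0) {
    suppressWarnings(build_groups(pairs, a, b, c_, config$beta, config$use_abs_beta))
  } else {
    empty_groups()
  }
  list(groups = structure(groups, n_pairs = nrow(pairs)), n_pairs = nrow(pairs))
}

#' Run the full grouping-scoring-modeling pipeline
#'
#' End-to-end driver: CpG preprocessing (missing-fraction, IQR and
#' exclusion-list filters), sample alignment across the three omics layers
#' and the labels, `n_outer_splits` outer Monte Carlo splits of
#' [run_split()], and aggregation of the per-split results into the
#' significant-group/feature tables, rank co-occurrence matrices, the
#' shared-gene group similarity matrix and the across-splits performance
#' summary.
#'
#' @param mirna,cpg,mrna [omics_matrix()] objects (any overlapping sample sets;
#'   they are aligned internally).
#' @param labels tibble with columns `sample_id`, `label` (exactly two classes).
#' @param config a [trimint_config()].
#' @param cpg_blocklists optional list of excluded CpG ID vectors.
#' @param preprocess run the CpG QC filters (set `FALSE` for data already
#'   QC'd upstream).
#' @return a `trimint_run` object; see [tidy.trimint_run()] for tabular
#'   access and [write_trimint_outputs()] for the on-disk layout.
#' @examples
#' \donttest{
#' sim <- simulate_triomics(n_samples_per_class = 30, n_background = 30, seed = 1)
#' cfg <- trimint_config(n_outer_splits = 5, min_group_frequency = 0, seed = 1)
#' run <- trimint_run(sim$mirna, sim$cpg, sim$mrna, sim$labels, cfg)
#' tidy(run, "groups")
#' }
#' @export
trimint_run <- function(mirna, cpg, mrna, labels, config = trimint_config(),
                        cpg_blocklists = list(), preprocess = TRUE) {
  validate_labels(labels)
  pre_reports <- NULL
  if (preprocess) {
    pp <- preprocess_cpg(cpg, config, cpg_blocklists)
    cpg <- pp$matrix
    pre_reports <- pp$reports
  }
  al <- align_samples(list(mirna = mirna, cpg = cpg, mrna = mrna), labels)
  mirna <- al$matrices$mirna; cpg <- al$matrices$cpg; mrna <- al$matrices$mrna
  labels <- al$labels

  shared_groups <- NULL
  if (config$leakage_mode == "global") {
    disc <- discover_groups(mirna, cpg, mrna, labels, config)
    shared_groups <- disc$groups
  }
  splits <- purrr::map(seq_len(config$n_outer_splits), function(i) {
    run_split(mirna, cpg, mrna, labels, config, split_index = i,
              groups = shared_groups)
  })

  groups_agg <- aggregate_groups(splits, config$min_group_frequency,
                                 count_top_k_only = config$count_top_k_only,
                                 top_k = config$top_k_groups)
  feats <- lapply(stats::setNames(nm = c("miRNA", "CpG", "gene")), function(kind) {
    aggregate_features(splits, kind, config$min_group_frequency,
                       count_top_k_only = config$count_top_k_only,
                       top_k = config$top_k_groups)
  })
  perf <- purrr::map_dfr(splits, function(s) {
    dplyr::mutate(s$performance, split = s$split_index, .before = 1)
  })
  rank_mats <- lapply(stats::setNames(nm = c("group", "miRNA", "CpG", "gene")),
                      function(kind) rank_matrix(splits, kind))
  sim <- if (nrow(groups_agg) >= 2) group_similarity(groups_agg) else NULL

  structure(list(
    splits = splits,
    groups = groups_agg,
    mirnas = feats$miRNA, cpgs = feats$CpG, genes = feats$gene,
    performance = perf,
    performance_summary = summarize_performance(perf),
    rank_matrices = rank_mats,
    similarity = sim,
    labels = labels,
    preprocess_reports = pre_reports,
    config = config
  ), class = "trimint_run")
}

# Across-splits performance summary: mean and standard error per cumulative
# rank; the unique-gene column reports the largest union observed at k and
# the average column its mean over splits.
summarize_performance <- function(perf) {
  if (nrow(perf) == 0) return(perf)
  se <- function(v) stats::sd(v) / sqrt(sum(!is.na(v)))
  perf |>
    dplyr::group_by(.data$cumulative_rank) |>
    dplyr::summarise(
      n_splits = dplyr::n(),
      n_unique_genes = max(.data$unique_gene_count),
      average_gene_n = mean(.data$unique_gene_count),
      dplyr::across(c("accuracy", "specificity", "sensitivity", "auc"),
                    list(mean = ~mean(.x, na.rm = TRUE), se = ~se(.x))),
      .groups = "drop"
    )
}

#' @export
print.trimint_split <- function(x, ...) {
  cat(sprintf("<trimint_split #%d> %d pairs, %d groups, %d train / %d test samples\n",
              x$split_index, x$n_pairs, x$n_groups,
              length(x$train_ids), length(x$test_ids)))
  invisible(x)
}

#' @export
print.trimint_run <- function(x, ...) {
  cat(sprintf("<trimint_run> %d splits, %d significant groups (frequency > %d)\n",
              length(x$splits), nrow(x$groups), x$config$min_group_frequency))
  if (nrow(x$groups) > 0) {
    print(utils::head(dplyr::select(x$groups, "group", "frequency",
                                    "average_score", "average_rank",
                                    "n_associated_genes"), 10))
  }
  invisible(x)
}
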
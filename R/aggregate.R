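# Long table of (split, group) occurrences from a list of trimint_split
# results; optionally restricted to each split's top-k groups.
split_occurrences <- function(splits, top_k_only = FALSE, top_k = Inf) {
  occ <- purrr::map_dfr(splits, function(s) {
    if (nrow(s$scored_groups) == 0) return(NULL)
    dplyr::mutate(s$scored_groups, split_index = s$split_index, .before = 1)
  })
  if (nrow(occ) == 0) {
    return(tibble::tibble(split_index = integer(), group = character(),
                          mirna_id = character(), cpg_id = character(),
                          r = numeric(), p_value = numeric(),
                          n_genes = integer(), genes = list(),
                          score = numeric(), rank = integer()))
  }
  if (top_k_only) occ <- dplyr::filter(occ, .data$rank <= top_k)
  occ
}

#' Aggregate groups over the outer splits
#'
#' One record per group name seen in strictly more than `min_group_frequency`
#' splits, with its split frequency, average score, average rank, the union of
#' associated genes over splits, summaries of the per-split gene-list sizes,
#' and the aligned split/rank lists. Sorted by decreasing frequency, then
#' increasing average rank.
#'
#' @param splits list of `trimint_split` results (see [run_split()]).
#' @param min_group_frequency groups appearing in `<= min_group_frequency`
#'   splits are dropped (the published floor is 5).
#' @param count_top_k_only count only appearances within each split's top-k.
#' @param top_k the k used when `count_top_k_only` is `TRUE`.
#' @return a tibble of aggregate group records.
#' @export
aggregate_groups <- function(splits, min_group_frequency = 5,
                             count_top_k_only = FALSE, top_k = 10) {
  occ <- split_occurrences(splits, count_top_k_only, top_k)
  agg <- occ |>
    dplyr::group_by(.data$group, .data$mirna_id, .data$cpg_id) |>
    dplyr::summarise(
      frequency = dplyr::n_distinct(.data$split_index),
      average_score = mean(.data$score),
      average_rank = mean(.data$rank),
      associated_genes = list(unique(unlist(.data$genes, use.names = FALSE))),
      min_gene_count = min(.data$n_genes),
      max_gene_count = max(.data$n_genes),
      median_gene_count = stats::median(.data$n_genes),
      split_list = list(.data$split_index),
      rank_list = list(.data$rank),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_associated_genes = lengths(.data$associated_genes),
                  .after = "associated_genes") |>
    dplyr::filter(.data$frequency > min_group_frequency) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$average_rank, .data$group)
  agg
}

#' Aggregate per-feature statistics over the outer splits
#'
#' Decomposes every retained group (frequency above the floor) into its
#' miRNA, CpG or gene constituents and tallies, per feature: `frequency`
#' (splits with at least one containing group), `total_frequency` (all
#' (split, group) occurrences), occurrence-weighted average score and rank,
#' the associated counterpart feature lists, and the aligned group/rank/split
#' lists.
#'
#' @inheritParams aggregate_groups
#' @param kind `"miRNA"`, `"CpG"` or `"gene"`.
#' @return a tibble of feature aggregate records sorted by decreasing
#'   frequency, then total frequency, then ID.
#' @export
aggregate_features <- function(splits, kind = c("miRNA", "CpG", "gene"),
                               min_group_frequency = 5,
                               count_top_k_only = FALSE, top_k = 10) {
  kind <- match.arg(kind)
  occ <- split_occurrences(splits, count_top_k_only, top_k)
  retained <- aggregate_groups(splits, min_group_frequency,
                               count_top_k_only, top_k)$group
  occ <- dplyr::filter(occ, .data$group %in% retained)
  occ <- switch(kind,
    miRNA = dplyr::mutate(occ, feature_id = .data$mirna_id),
    CpG = dplyr::mutate(occ, feature_id = .data$cpg_id),
    gene = tidyr::unnest(dplyr::mutate(occ, feature_id = .data$genes),
                         "feature_id")
  )
  if (nrow(occ) == 0) {
    return(tibble::tibble(feature_id = character(), feature_kind = character(),
                          frequency = integer(), total_frequency = integer(),
                          average_score = numeric(), average_rank = numeric(),
                          group_list = list(), n_groups = integer(),
                          associated_mirnas = list(), associated_cpgs = list(),
                          associated_genes = list(),
                          rank_list = list(), split_list = list()))
  }
  occ |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      feature_kind = kind,
      frequency = dplyr::n_distinct(.data$split_index),
      total_frequency = dplyr::n(),
      average_score = mean(.data$score),
      average_rank = mean(.data$rank),
      group_list = list(unique(.data$group)),
      n_groups = dplyr::n_distinct(.data$group),
      associated_mirnas = list(unique(.data$mirna_id)),
      associated_cpgs = list(unique(.data$cpg_id)),
      associated_genes = list(unique(unlist(.data$genes, use.names = FALSE))),
      rank_list = list(.data$rank),
      split_list = list(.data$split_index),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$frequency),
                   dplyr::desc(.data$total_frequency), .data$feature_id)
}

#' Best-rank co-occurrence matrix over splits
#'
#' For each entity (group, miRNA, CpG or gene) ever detected, the best
#' (minimum) rank among the groups containing it in each split, `NA` where
#' absent — the data behind the rank heatmaps. Rows come ordered by average
#' rank; a split (column) ordering from hierarchical clustering (Euclidean
#' distance on rank vectors with absences imputed one worse than the worst
#' observed rank, average linkage) is attached.
#'
#' @inheritParams aggregate_groups
#' @param kind `"group"`, `"miRNA"`, `"CpG"` or `"gene"`.
#' @return a `trimint_rank_matrix`: list with `matrix` (entities x splits),
#'   `average_rank`, `column_order`.
#' @export
rank_matrix <- function(splits, kind = c("group", "miRNA", "CpG", "gene")) {
  kind <- match.arg(kind)
  occ <- split_occurrences(splits)
  occ <- switch(kind,
    group = dplyr::mutate(occ, entity = .data$group),
    miRNA = dplyr::mutate(occ, entity = .data$mirna_id),
    CpG = dplyr::mutate(occ, entity = .data$cpg_id),
    gene = if (nrow(occ) > 0) {
      tidyr::unnest(dplyr::mutate(occ, entity = .data$genes), "entity")
    } else {
      dplyr::mutate(occ, entity = character())
    }
  )
  all_splits <- sort(vapply(splits, function(s) s$split_index, integer(1)))
  best <- occ |>
    dplyr::group_by(.data$entity, .data$split_index) |>
    dplyr::summarise(best_rank = min(.data$rank), .groups = "drop")
  entities <- sort(unique(best$entity), method = "radix")
  m <- matrix(NA_real_, nrow = length(entities), ncol = length(all_splits),
              dimnames = list(entities, paste0("split_", all_splits)))
  if (nrow(best) > 0) {
    m[cbind(match(best$entity, entities), match(best$split_index, all_splits))] <-
      best$best_rank
  }
  avg <- rowMeans(m, na.rm = TRUE)
  m <- m[order(avg, rownames(m), method = "radix"), , drop = FALSE]
  avg <- avg[rownames(m)]
  structure(list(matrix = m, average_rank = avg,
                 column_order = cluster_columns(m), kind = kind),
            class = "trimint_rank_matrix")
}

# Average-linkage clustering order of the columns; absences imputed one worse
# than the worst observed rank (clustering only — the matrix keeps its NAs).
cluster_columns <- function(m) {
  if (ncol(m) < 3 || nrow(m) == 0) return(seq_len(ncol(m)))
  worst <- suppressWarnings(max(m, na.rm = TRUE))
  if (!is.finite(worst)) return(seq_len(ncol(m)))
  imp <- m
  imp[is.na(imp)] <- worst + 1
  stats::hclust(stats::dist(t(imp), method = "euclidean"),
                method = "average")$order
}

#' @export
print.trimint_rank_matrix <- function(x, ...) {
  cat(sprintf("<trimint_rank_matrix> kind=%s: %d entities x %d splits\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Shared-gene similarity between aggregated groups
#'
#' Jaccard similarity on the groups' union gene sets: the intersection size
#' divided by the union size for every pair of groups, unit diagonal. An
#' average-linkage hierarchical clustering order (Euclidean distance on the
#' similarity rows) is attached for heatmap display.
#'
#' @param agg tibble from [aggregate_groups()] with at least 2 rows.
#' @return a `trimint_similarity`: list with `matrix` (symmetric, in
#'   `[0, 1]`) and `order`.
#' @export
group_similarity <- function(agg) {
  stopifnot(nrow(agg) >= 2)
  sets <- agg$associated_genes
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(agg$group, agg$group)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      m[i, j] <- m[j, i] <- if (uni == 0) 0 else inter / uni
    }
  }
  ord <- if (n >= 3) {
    stats::hclust(stats::dist(m, method = "euclidean"), method = "average")$order
  } else {
    seq_len(n)
  }
  structure(list(matrix = m, order = ord), class = "trimint_similarity")
}

#' @export
print.trimint_similarity <- function(x, ...) {
  cat(sprintf("<trimint_similarity> %d groups\n", nrow(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Per-split membership counts of one group's genes
#'
#' For every gene ever belonging to the named group, the number of splits in
#' which it was a member — the data behind per-group gene-frequency bar
#' charts.
#'
#' @inheritParams aggregate_groups
#' @param group_name a group name (`"<mirna>_<cpg>"`) detected in >= 1 split.
#' @return a tibble with columns `gene_id`, `n_splits`, sorted by decreasing
#'   count then ID.
#' @export
gene_frequency_per_group <- function(splits, group_name) {
  occ <- split_occurrences(splits)
  occ <- dplyr::filter(occ, .data$group == group_name)
  if (nrow(occ) == 0) {
    rlang::abort(sprintf("Group '%s' was not detected in any split.", group_name))
  }
  occ |>
    tidyr::unnest(genes) |>
    dplyr::distinct(.data$split_index, .data$genes) |>
    dplyr::count(gene_id = .data$genes, name = "n_splits") |>
    dplyr::arrange(dplyr::desc(.data$n_splits), .data$gene_id)
}
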
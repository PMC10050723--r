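#' Plot the across-splits performance summary
#'
#' Mean held-out metric per cumulative rank with +/- one standard error of
#' the mean, one line per metric.
#'
#' @param run a `trimint_run`.
#' @param metrics metrics to show.
#' @return a ggplot.
#' @export
plot_performance <- function(run, metrics = c("accuracy", "specificity",
                                              "sensitivity", "auc")) {
  s <- run$performance_summary
  long <- tidyr::pivot_longer(
    s, cols = dplyr::matches("_(mean|se)$"),
    names_to = c("metric", ".value"), names_pattern = "(.*)_(mean|se)")
  long <- dplyr::filter(long, .data$metric %in% metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cumulative_rank, y = .data$mean,
                                     colour = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = .data$metric),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_x_continuous(breaks = unique(long$cumulative_rank)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "cumulative groups (k)", y = "held-out metric",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trimint_run <- function(object, ...) plot_performance(object, ...)

#' Plot a rank co-occurrence heatmap
#'
#' Entities in rows (ordered by average rank), splits in columns (ordered by
#' the attached hierarchical clustering); tile colour encodes the best rank,
#' absences are blank.
#'
#' @param x a `trimint_rank_matrix` from [rank_matrix()].
#' @return a ggplot.
#' @export
plot_rank_heatmap <- function(x) {
  m <- x$matrix[, x$column_order, drop = FALSE]
  df <- tibble::as_tibble(m, rownames = "entity") |>
    tidyr::pivot_longer(-"entity", names_to = "split", values_to = "rank") |>
    dplyr::mutate(entity = factor(.data$entity, levels = rev(rownames(m))),
                  split = factor(.data$split, levels = colnames(m)))
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$rank)),
                  ggplot2::aes(x = .data$split, y = .data$entity,
                               fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "split", y = NULL, fill = "best rank") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.trimint_rank_matrix <- function(object, ...) plot_rank_heatmap(object)

#' Plot the group-similarity heatmap
#'
#' Jaccard shared-gene similarity between aggregated groups, rows and
#' columns in the attached clustering order.
#'
#' @param x a `trimint_similarity` from [group_similarity()].
#' @return a ggplot.
#' @export
plot_group_similarity <- function(x) {
  lev <- rownames(x$matrix)[x$order]
  df <- tibble::as_tibble(x$matrix, rownames = "group_a") |>
    tidyr::pivot_longer(-"group_a", names_to = "group_b",
                        values_to = "similarity") |>
    dplyr::mutate(group_a = factor(.data$group_a, levels = lev),
                  group_b = factor(.data$group_b, levels = rev(lev)))
  ggplot2::ggplot(df, ggplot2::aes(.data$group_a, .data$group_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.trimint_similarity <- function(object, ...) plot_group_similarity(object)

#' Plot gene membership frequencies for one group
#'
#' Bar chart of the number of splits in which each gene belonged to the
#' group.
#'
#' @param splits list of `trimint_split` results (or a `trimint_run`).
#' @param group_name group name.
#' @return a ggplot.
#' @export
plot_gene_frequency <- function(splits, group_name) {
  if (inherits(splits, "trimint_run")) splits <- splits$splits
  df <- gene_frequency_per_group(splits, group_name)
  df$gene_id <- factor(df$gene_id, levels = df$gene_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_id, .data$n_splits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = group_name, x = NULL, y = "splits containing gene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
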
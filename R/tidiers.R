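#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run into one of its result tables
#'
#' @param x a `trimint_run` from [trimint_run()].
#' @param type which table: aggregated `"groups"` (default), `"mirnas"`,
#'   `"cpgs"`, `"genes"`, the per-split `"performance"` table, or `"pairs"`
#'   (the distinct miRNA-CpG pairs behind the splits' groups).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.trimint_run <- function(x, type = c("groups", "mirnas", "cpgs", "genes",
                                         "performance", "pairs"), ...) {
  type <- match.arg(type)
  switch(type,
    groups = x$groups,
    mirnas = x$mirnas,
    cpgs = x$cpgs,
    genes = x$genes,
    performance = x$performance,
    pairs = split_occurrences(x$splits) |>
      dplyr::distinct(.data$group, .data$mirna_id, .data$cpg_id, .data$r,
                      .data$p_value)
  )
}

#' One-row summary of a pipeline run
#'
#' @param x a `trimint_run`.
#' @param ... unused.
#' @return a one-row tibble: split count, pair/group detection counts,
#'   significant-table sizes, and the top cumulative model's mean held-out
#'   accuracy and AUC over splits.
#' @export
glance.trimint_run <- function(x, ...) {
  perf1 <- dplyr::filter(x$performance, .data$cumulative_rank == 1)
  tibble::tibble(
    n_splits = length(x$splits),
    n_samples = nrow(x$labels),
    mean_pairs_per_split = mean(vapply(x$splits, `[[`, integer(1), "n_pairs")),
    mean_groups_per_split = mean(vapply(x$splits, `[[`, integer(1), "n_groups")),
    n_significant_groups = nrow(x$groups),
    n_significant_mirnas = nrow(x$mirnas),
    n_significant_cpgs = nrow(x$cpgs),
    n_significant_genes = nrow(x$genes),
    mean_accuracy_k1 = if (nrow(perf1)) mean(perf1$accuracy) else NA_real_,
    mean_auc_k1 = if (nrow(perf1)) mean(perf1$auc, na.rm = TRUE) else NA_real_
  )
}
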
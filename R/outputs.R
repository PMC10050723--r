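#' Write a result table as deterministic TSV
#'
#' Tab-separated with a header row; rows in the order given; doubles rendered
#' with 6 significant digits and list-columns joined with `"; "`, so two runs
#' from the same inputs and seed produce byte-identical files.
#'
#' @param df a data frame / tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trimint_table <- function(df, path) {
  out <- dplyr::mutate(tibble::as_tibble(df), dplyr::across(
    dplyr::everything(), render_column))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

render_column <- function(col) {
  if (is.list(col)) {
    vapply(col, function(v) paste(render_column(unlist(v)), collapse = "; "),
           character(1))
  } else if (is.double(col)) {
    ifelse(is.na(col), "NA", formatC(col, digits = 6, format = "g"))
  } else {
    as.character(col)
  }
}

#' Write every output table of a pipeline run
#'
#' Materialises a [trimint_run()] as a directory of tab-separated tables:
#' `performance_table.tsv` (per split and cumulative rank) and
#' `performance_summary.tsv` (mean and standard error over splits),
#' `significant_groups.tsv`, `significant_mirnas.tsv`, `significant_cpgs.tsv`,
#' `significant_genes.tsv`, `group_similarity.tsv` (with
#' `group_similarity_order.tsv`), `rank_matrix_{groups,mirnas,cpgs,genes}.tsv`
#' (each with a `*_column_order.tsv` companion holding the clustered split
#' order), the resolved `run_config.yaml`, and a `run.log` of per-stage
#' counts.
#'
#' @param run a `trimint_run`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trimint_outputs <- function(run, dir) {
  stopifnot(inherits(run, "trimint_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)

  write_trimint_table(run$performance, p("performance_table.tsv"))
  write_trimint_table(run$performance_summary, p("performance_summary.tsv"))
  write_trimint_table(run$groups, p("significant_groups.tsv"))
  write_trimint_table(run$mirnas, p("significant_mirnas.tsv"))
  write_trimint_table(run$cpgs, p("significant_cpgs.tsv"))
  write_trimint_table(run$genes, p("significant_genes.tsv"))

  file_kind <- c(group = "groups", miRNA = "mirnas", CpG = "cpgs", gene = "genes")
  for (kind in names(run$rank_matrices)) {
    rm_ <- run$rank_matrices[[kind]]
    df <- tibble::as_tibble(rm_$matrix, rownames = "entity")
    df$average_rank <- unname(rm_$average_rank)
    write_trimint_table(df, p(sprintf("rank_matrix_%s.tsv", file_kind[[kind]])))
    write_trimint_table(
      tibble::tibble(position = seq_along(rm_$column_order),
                     split_column = colnames(rm_$matrix)[rm_$column_order]),
      p(sprintf("rank_matrix_%s_column_order.tsv", file_kind[[kind]])))
  }
  if (!is.null(run$similarity)) {
    df <- tibble::as_tibble(run$similarity$matrix, rownames = "group")
    write_trimint_table(df, p("group_similarity.tsv"))
    write_trimint_table(
      tibble::tibble(position = seq_along(run$similarity$order),
                     group = rownames(run$similarity$matrix)[run$similarity$order]),
      p("group_similarity_order.tsv"))
  }

  cfg <- unclass(run$config)
  cfg$score_metric_weights <- as.list(cfg$score_metric_weights)
  cfg$positive_label <- cfg$positive_label %||%
    sort(unique(run$labels$label), method = "radix")[1]
  yaml::write_yaml(cfg, p("run_config.yaml"))

  log_lines <- c(
    sprintf("samples: %d", nrow(run$labels)),
    sprintf("outer splits: %d", length(run$splits)),
    if (!is.null(run$preprocess_reports)) {
      sprintf("preprocess %s: %d -> %d features",
              run$preprocess_reports$stage,
              run$preprocess_reports$features_in,
              run$preprocess_reports$features_out)
    },
    vapply(run$splits, function(s) {
      sprintf("split %d: %d pairs, %d groups", s$split_index, s$n_pairs,
              s$n_groups)
    }, character(1)),
    sprintf("significant groups (frequency > %d): %d",
            run$config$min_group_frequency, nrow(run$groups))
  )
  writeLines(log_lines, p("run.log"))
  invisible(dir)
}
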
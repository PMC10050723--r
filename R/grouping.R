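#' Build cross-omics gene groups from miRNA-CpG pairs
#'
#' The grouping (G) stage: for each detected miRNA-CpG pair, collect every
#' mRNA feature whose correlation with the miRNA *and* with the CpG exceeds
#' `beta`. By default the condition is on the absolute correlation
#' (`|r| > beta`), since miRNA repression and methylation silencing make
#' negative associations biologically meaningful; `use_abs = FALSE` restores
#' the literal signed reading `r > beta`. Pairs yielding no qualifying gene
#' are dropped. Groups are named `"<mirna_id>_<cpg_id>"`.
#'
#' Genes within a group are ordered by decreasing `min(|r_mirna|, |r_cpg|)`
#' (the weaker of the two links), ties broken by gene ID, so group contents
#' are reproducible.
#'
#' @param pairs tibble from [detect_pairs()] (columns `mirna_id`, `cpg_id`,
#'   `r`, `p_value`).
#' @param mirna,cpg,mrna sample-aligned [omics_matrix()] objects.
#' @param beta group correlation threshold in (0, 1], strict.
#' @param use_abs apply the threshold to `|r|` (default) or to signed `r`.
#' @return a tibble with one row per non-empty group: `group`, `mirna_id`,
#'   `cpg_id`, `r`, `p_value`, `n_genes`, `genes` (list-column of ordered
#'   gene IDs).
#' @export
build_groups <- function(pairs, mirna, cpg, mrna, beta = 0.6, use_abs = TRUE) {
  stopifnot(identical(colnames(mirna), colnames(mrna)),
            identical(colnames(cpg), colnames(mrna)))
  if (nrow(pairs) == 0) {
    return(empty_groups())
  }
  gene_sd_ok <- row_sds(mrna) > 0
  genes_m <- om_features(mrna, which(gene_sd_ok))
  # one correlation scan per distinct pair member, reused across pairs
  r_gene_mir <- cross_correlation(genes_m, om_features(mirna, unique(pairs$mirna_id)))
  r_gene_cpg <- cross_correlation(genes_m, om_features(cpg, unique(pairs$cpg_id)))
  cond <- if (use_abs) function(r) abs(r) > beta else function(r) r > beta
  rows <- purrr::pmap(pairs, function(mirna_id, cpg_id, r, p_value, ...) {
    ra <- r_gene_mir[, mirna_id]
    rb <- r_gene_cpg[, cpg_id]
    in_group <- cond(ra) & cond(rb)
    if (!any(in_group)) return(NULL)
    strength <- pmin(abs(ra[in_group]), abs(rb[in_group]))
    ids <- rownames(genes_m)[in_group]
    ord <- order(-strength, ids, method = "radix")
    tibble::tibble(group = paste0(mirna_id, "_", cpg_id),
                   mirna_id = mirna_id, cpg_id = cpg_id,
                   r = r, p_value = p_value,
                   n_genes = sum(in_group), genes = list(ids[ord]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warning("build_groups: no pair yielded a qualifying gene; zero groups.")
    return(empty_groups())
  }
  out
}

empty_groups <- function() {
  tibble::tibble(group = character(), mirna_id = character(),
                 cpg_id = character(), r = numeric(), p_value = numeric(),
                 n_genes = integer(), genes = list())
}

#' Build one group for a single miRNA-CpG pair
#'
#' Convenience wrapper over [build_groups()] for a single pair.
#'
#' @param mirna_id,cpg_id pair member feature IDs.
#' @inheritParams build_groups
#' @return a one-row group tibble, or `NULL` when no gene qualifies.
#' @export
build_group <- function(mirna_id, cpg_id, mirna, cpg, mrna, beta = 0.6,
                        use_abs = TRUE) {
  pr <- pearson_cor_test(unclass(mirna)[mirna_id, ], unclass(cpg)[cpg_id, ])
  pair <- tibble::tibble(mirna_id = mirna_id, cpg_id = cpg_id,
                         r = pr$r, p_value = pr$p_value)
  out <- suppressWarnings(
    build_groups(pair, mirna, cpg, mrna, beta = beta, use_abs = use_abs))
  if (nrow(out) == 0) NULL else out
}
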
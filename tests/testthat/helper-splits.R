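# Hand-constructed split results for aggregation tests: each entry gives the
# groups detected in one split as name -> (rank, score, genes).
fake_split <- function(index, groups) {
  ids <- names(groups) %||% character(0)
  scored <- tibble::tibble(
    group = ids,
    .rows = length(ids),
    mirna_id = vapply(strsplit(ids, "_"), `[`, character(1), 1),
    cpg_id = vapply(strsplit(ids, "_"), `[`, character(1), 2),
    r = 0.8, p_value = 1e-5,
    n_genes = unname(vapply(groups, function(g) length(g$genes), integer(1))),
    genes = unname(lapply(groups, `[[`, "genes")),
    score = unname(vapply(groups, `[[`, numeric(1), "score")),
    rank = unname(vapply(groups, `[[`, integer(1), "rank"))
  )
  structure(list(split_index = index, seed = index, scored_groups = scored,
                 performance = tibble::tibble(), n_pairs = length(groups),
                 n_groups = length(groups), train_ids = character(),
                 test_ids = character()),
            class = "trimint_split")
}

g <- function(rank, score, genes) list(rank = as.integer(rank), score = score,
                                       genes = genes)

make_fake_splits <- function() {
  # m1_c1 in 7 splits; m2_c2 in 6; m3_c3 in 5 (boundary); m4_c4 in 1
  lapply(1:10, function(i) {
    gs <- list()
    if (i <= 7) gs[["m1_c1"]] <- g(1, 0.9, c("ga", "gb", if (i %% 2) "gc"))
    if (i <= 6) gs[["m2_c2"]] <- g(2, 0.8, c("gb", "gd"))
    if (i <= 5) gs[["m3_c3"]] <- g(3, 0.7, "ge")
    if (i == 1) gs[["m4_c4"]] <- g(4, 0.6, "gf")
    fake_split(i, gs)
  })
}
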
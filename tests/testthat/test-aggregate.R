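test_that("group aggregation filters the frequency boundary and summarises gene lists", {
  agg <- aggregate_groups(make_fake_splits(), min_group_frequency = 5)
  # frequency 5 is dropped (strictly-greater rule), 6 and 7 are kept
  expect_setequal(agg$group, c("m1_c1", "m2_c2"))
  m1 <- dplyr::filter(agg, group == "m1_c1")
  expect_identical(m1$frequency, 7L)
  expect_identical(m1$split_list[[1]], 1:7)
  expect_identical(m1$rank_list[[1]], rep(1L, 7))
  expect_equal(m1$average_rank, 1)
  expect_equal(m1$average_score, 0.9)
  expect_setequal(m1$associated_genes[[1]], c("ga", "gb", "gc"))
  expect_identical(m1$n_associated_genes, 3L)
  expect_identical(m1$min_gene_count, 2L)
  expect_identical(m1$max_gene_count, 3L)
  expect_equal(m1$median_gene_count, 3)
  # threshold 0 retains everything seen at least once
  expect_identical(nrow(aggregate_groups(make_fake_splits(), 0)), 4L)
})

test_that("feature aggregation counts frequency vs total frequency and reconciles with groups", {
  splits <- lapply(1:3, function(i) {
    fake_split(i, list(
      mShared_c1 = g(1, 0.9, c("gx", "gy")),
      mShared_c2 = g(2, 0.8, "gx")
    ))
  })
  mir <- aggregate_features(splits, "miRNA", min_group_frequency = 0)
  expect_identical(nrow(mir), 1L)
  expect_identical(mir$frequency, 3L)        # splits with >= 1 group
  expect_identical(mir$total_frequency, 6L)  # (split, group) occurrences
  expect_setequal(mir$group_list[[1]], c("mShared_c1", "mShared_c2"))
  expect_setequal(mir$associated_cpgs[[1]], c("c1", "c2"))
  expect_setequal(mir$associated_genes[[1]], c("gx", "gy"))
  expect_equal(mir$average_rank, 1.5)

  genes <- aggregate_features(splits, "gene", min_group_frequency = 0)
  gx <- dplyr::filter(genes, feature_id == "gx")
  expect_identical(gx$total_frequency, 6L)
  expect_identical(gx$frequency, 3L)
  gy <- dplyr::filter(genes, feature_id == "gy")
  expect_identical(gy$rank_list[[1]], rep(1L, 3))

  # conservation: total (split, group) occurrences agree between the group
  # table and the miRNA decomposition
  agg <- aggregate_groups(splits, 0)
  expect_identical(sum(agg$frequency), sum(mir$total_frequency))

  cpgs <- aggregate_features(splits, "CpG", min_group_frequency = 0)
  expect_identical(sum(cpgs$total_frequency), sum(agg$frequency))
})

test_that("feature decomposition only sees groups above the frequency floor", {
  splits <- make_fake_splits()
  genes <- aggregate_features(splits, "gene", min_group_frequency = 5)
  expect_false("ge" %in% genes$feature_id)  # only in the frequency-5 group
  expect_false("gf" %in% genes$feature_id)
  expect_true(all(c("ga", "gb", "gc", "gd") %in% genes$feature_id))
})

test_that("rank matrices record best ranks with absences and support clustering", {
  splits <- make_fake_splits()
  rm_g <- rank_matrix(splits, "group")
  expect_identical(dim(rm_g$matrix), c(4L, 10L))
  expect_identical(unname(rm_g$matrix["m1_c1", 1:7]), rep(1, 7))
  expect_true(all(is.na(rm_g$matrix["m1_c1", 8:10])))
  expect_true(all(is.na(rm_g$matrix["m4_c4", 2:10])))
  # rows ordered by average rank
  expect_identical(rownames(rm_g$matrix)[1], "m1_c1")
  expect_identical(unname(rm_g$average_rank["m3_c3"]), 3)
  expect_setequal(rm_g$column_order, 1:10)

  # a gene in two groups gets the better (smaller) rank
  splits2 <- lapply(1:2, function(i) fake_split(i, list(
    m1_c1 = g(1, 0.9, "shared"), m2_c2 = g(2, 0.8, "shared"))))
  rm_gene <- rank_matrix(splits2, "gene")
  expect_identical(unname(rm_gene$matrix["shared", ]), c(1, 1))

  # entity absent from all splits cannot appear
  expect_false("zz" %in% rownames(rm_g$matrix))
})

test_that("column clustering matches the brute-force average-linkage oracle", {
  m <- rbind(c(1, 1, 5, 5, 3), c(2, 1, 6, 5, 4), c(1, 2, 5, 6, 3),
             c(9, 9, 1, 1, 9))
  rownames(m) <- paste0("e", 1:4)
  colnames(m) <- paste0("split_", 1:5)
  ord <- trimint:::cluster_columns(m)
  d <- as.matrix(stats::dist(t(m)))
  merges <- oracle_average_linkage(d)
  # same merge history as stats::hclust at average linkage
  h <- stats::hclust(stats::dist(t(m)), "average")
  expect_equal(sort(vapply(merges, `[[`, numeric(1), "height")),
               sort(h$height), tolerance = 1e-12)
  expect_true(order_respects_tree(ord, merges))
})

test_that("group similarity is the Jaccard index with a valid clustering order", {
  agg <- tibble::tibble(
    group = c("gA", "gB", "gC", "gD", "gE"),
    associated_genes = list(c("a", "b", "c"), c("b", "c", "d"), c("a", "b", "c"),
                            c("x", "y"), c("a", "x")))
  sim <- group_similarity(agg)
  m <- sim$matrix
  expect_equal(m["gA", "gB"], 0.5)     # {a,b,c} vs {b,c,d} -> 2/4
  expect_equal(m["gA", "gC"], 1)       # identical sets
  expect_equal(m["gA", "gD"], 0)       # disjoint sets
  expect_equal(m["gA", "gE"], 1 / 4)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 1))
  expect_true(all(m >= 0 & m <= 1))
  merges <- oracle_average_linkage(as.matrix(stats::dist(m)))
  expect_true(order_respects_tree(sim$order, merges))
  expect_error(group_similarity(agg[1, ]))
})

test_that("per-group gene frequencies count split memberships exactly", {
  splits <- make_fake_splits()
  freq <- gene_frequency_per_group(splits, "m1_c1")
  expect_identical(dplyr::filter(freq, gene_id == "ga")$n_splits, 7L)
  expect_identical(dplyr::filter(freq, gene_id == "gc")$n_splits, 4L)  # odd splits 1,3,5,7
  expect_false("ge" %in% freq$gene_id)
  # double-counting identity: sum over genes == sum over splits of group size
  occ <- trimint:::split_occurrences(splits)
  sizes <- dplyr::filter(occ, group == "m1_c1")$n_genes
  expect_identical(sum(freq$n_splits), sum(sizes))
  expect_error(gene_frequency_per_group(splits, "nope_nope"), "not detected")
})
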
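test_that("groups contain exactly the genes satisfying both correlation conditions", {
  sim <- small_sim(seed = 61)
  pairs <- detect_pairs(sim$mirna, sim$cpg, 0.6, 0.05)
  groups <- build_groups(pairs, sim$mirna, sim$cpg, sim$mrna, beta = 0.6)
  expect_gt(nrow(groups), 0)
  # self-consistency: re-verify every member (and every non-member) by
  # direct correlation against both pair members
  for (g in seq_len(nrow(groups))) {
    a_vec <- unclass(sim$mirna)[groups$mirna_id[g], ]
    b_vec <- unclass(sim$cpg)[groups$cpg_id[g], ]
    in_set <- vapply(rownames(sim$mrna), function(gene) {
      c_vec <- unclass(sim$mrna)[gene, ]
      abs(oracle_pearson(a_vec, c_vec)$r) > 0.6 &&
        abs(oracle_pearson(c_vec, b_vec)$r) > 0.6
    }, logical(1))
    expect_setequal(groups$genes[[g]], rownames(sim$mrna)[in_set])
    expect_identical(groups$group[g],
                     paste0(groups$mirna_id[g], "_", groups$cpg_id[g]))
    expect_identical(groups$n_genes[g], length(groups$genes[[g]]))
    expect_false(anyDuplicated(groups$genes[[g]]) > 0)
  }
})

test_that("planted modules are recovered without cross-talk", {
  sim <- simulate_triomics(n_samples_per_class = 50, n_background = 50, seed = 71)
  pairs <- detect_pairs(sim$mirna, sim$cpg, 0.6, 0.05)
  groups <- build_groups(pairs, sim$mirna, sim$cpg, sim$mrna, beta = 0.6)
  for (m in seq_len(nrow(sim$truth$modules))) {
    nm <- planted_group_names(sim)[m]
    row <- dplyr::filter(groups, group == nm)
    expect_identical(nrow(row), 1L)
    expect_setequal(row$genes[[1]], sim$truth$modules$genes[[m]])
  }
})

test_that("gene sets are monotone nested in beta", {
  sim <- small_sim(seed = 81)
  pairs <- detect_pairs(sim$mirna, sim$cpg, 0.6, 0.05)
  gsets <- lapply(c(0.4, 0.6, 0.8), function(beta) {
    g <- suppressWarnings(
      build_groups(pairs, sim$mirna, sim$cpg, sim$mrna, beta = beta))
    stats::setNames(g$genes, g$group)
  })
  for (nm in names(gsets[[3]])) {
    expect_true(all(gsets[[3]][[nm]] %in% gsets[[2]][[nm]]))
  }
  for (nm in names(gsets[[2]])) {
    expect_true(all(gsets[[2]][[nm]] %in% gsets[[1]][[nm]]))
  }
})

test_that("degenerate grouping inputs behave as contracted", {
  sim <- small_sim(seed = 91)
  pairs <- detect_pairs(sim$mirna, sim$cpg, 0.6, 0.05)
  # beta = 1 can never be exceeded strictly -> no groups
  expect_warning(g1 <- build_groups(pairs, sim$mirna, sim$cpg, sim$mrna, beta = 1),
                 "zero groups")
  expect_identical(nrow(g1), 0L)
  # empty pair list -> empty group list
  expect_identical(nrow(build_groups(pairs[0, ], sim$mirna, sim$cpg, sim$mrna)), 0L)
  # build_group single-pair wrapper agrees with build_groups
  one <- build_group(pairs$mirna_id[1], pairs$cpg_id[1],
                     sim$mirna, sim$cpg, sim$mrna, beta = 0.6)
  expect_identical(one$genes[[1]],
                   dplyr::filter(build_groups(pairs, sim$mirna, sim$cpg, sim$mrna),
                                 group == one$group)$genes[[1]])
  expect_null(build_group(pairs$mirna_id[1], pairs$cpg_id[1],
                          sim$mirna, sim$cpg, sim$mrna, beta = 0.999999))
})

test_that("signed mode only keeps positively correlated genes", {
  set.seed(15)
  n <- 60
  z <- rnorm(n)
  a <- make_om(rbind(z + rnorm(n, sd = 0.1)), role = "miRNA", features = "mir1")
  b <- make_om(rbind(z + rnorm(n, sd = 0.1)), role = "CpG", features = "cg1",
               samples = sprintf("s%d", 1:n))
  c_ <- make_om(rbind(z + rnorm(n, sd = 0.1), -z + rnorm(n, sd = 0.1)),
                role = "mRNA", features = c("gPos", "gNeg"),
                samples = sprintf("s%d", 1:n))
  pairs <- detect_pairs(a, b, 0.6, 0.05)
  abs_mode <- build_groups(pairs, a, b, c_, beta = 0.6, use_abs = TRUE)
  expect_setequal(abs_mode$genes[[1]], c("gPos", "gNeg"))
  signed <- build_groups(pairs, a, b, c_, beta = 0.6, use_abs = FALSE)
  expect_identical(signed$genes[[1]], "gPos")
})

test_that("two pairs sharing a miRNA give two distinct groups with possibly overlapping genes", {
  set.seed(25)
  n <- 60
  z <- rnorm(n)
  a <- make_om(rbind(z + rnorm(n, sd = 0.1)), role = "miRNA", features = "mir1")
  b <- make_om(rbind(z + rnorm(n, sd = 0.1), z + rnorm(n, sd = 0.1)),
               role = "CpG", features = c("cg1", "cg2"),
               samples = sprintf("s%d", 1:n))
  c_ <- make_om(rbind(z + rnorm(n, sd = 0.1)), role = "mRNA", features = "g1",
                samples = sprintf("s%d", 1:n))
  pairs <- detect_pairs(a, b, 0.6, 0.05)
  groups <- build_groups(pairs, a, b, c_, beta = 0.6)
  expect_identical(nrow(groups), 2L)
  expect_identical(groups$genes[[1]], groups$genes[[2]])
})
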
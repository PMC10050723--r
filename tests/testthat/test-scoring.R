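# Hand-built group tibbles for scoring tests.
fake_groups <- function(gene_sets) {
  tibble::tibble(
    group = names(gene_sets),
    mirna_id = paste0("mir_", names(gene_sets)),
    cpg_id = paste0("cg_", names(gene_sets)),
    r = 0.9, p_value = 1e-6,
    n_genes = lengths(gene_sets),
    genes = unname(gene_sets)
  )
}

separable_mrna <- function(n_per_class = 20, extra_noise_genes = 3, seed = 1) {
  withr::with_seed(seed, {
    vals <- rbind(sep = rep(c(0, 1), each = n_per_class),
                  matrix(rnorm(extra_noise_genes * 2 * n_per_class),
                         extra_noise_genes,
                         dimnames = list(paste0("noise", seq_len(extra_noise_genes)))))
  })
  make_om(vals, role = "mRNA",
          features = rownames(vals))
}

test_that("a perfectly separable group scores 1 and outranks noise", {
  m <- separable_mrna()
  labs <- two_class_labels(colnames(m), 20, classes = c("N", "P"))
  cfg <- trimint_config(n_outer_splits = 1, inner_cv_iterations = 3, seed = 5)
  scored <- score_groups(fake_groups(list(sep = "sep", noise = c("noise1", "noise2"))),
                         m, labs, cfg)
  expect_equal(dplyr::filter(scored, group == "sep")$score, 1)
  expect_identical(dplyr::filter(scored, group == "sep")$rank, 1L)
  expect_identical(sort(scored$rank), seq_len(nrow(scored)))
  # score reconciles with the per-iteration scores under accuracy weights
  expect_equal(scored$score,
               vapply(scored$per_iteration_scores, mean, numeric(1)))

  # equal accuracy/auc weights on the separable group still give 1
  cfg2 <- trimint_config(n_outer_splits = 1, inner_cv_iterations = 3, seed = 5,
                         score_metric_weights = c(accuracy = 0.5, auc = 0.5))
  scored2 <- score_groups(fake_groups(list(sep = "sep")), m, labs, cfg2)
  expect_equal(scored2$score, 1)
})

test_that("identical gene sets score identically and ties break by size then name", {
  m <- separable_mrna(seed = 2)
  labs <- two_class_labels(colnames(m), 20)
  cfg <- trimint_config(inner_cv_iterations = 3, seed = 9)
  scored <- score_groups(
    fake_groups(list(zz_twin = "sep", aa_twin = "sep")), m, labs, cfg)
  expect_equal(scored$score[1], scored$score[2])
  expect_identical(scored$group, c("aa_twin", "zz_twin"))
  # larger gene set wins the tie against an equally scoring smaller one
  scored2 <- score_groups(
    fake_groups(list(small = "sep", big = c("sep", "noise1"))), m, labs, cfg)
  if (scored2$score[1] == scored2$score[2]) {
    expect_identical(scored2$group[1], "big")
  }
})

test_that("scoring under permuted labels stays near chance", {
  m <- separable_mrna(extra_noise_genes = 2)
  mean_scores <- vapply(1:20, function(s) {
    labs <- withr::with_seed(1000 + s,
      tibble::tibble(sample_id = colnames(m), label = sample(rep(c("N", "P"), 20))))
    cfg <- trimint_config(inner_cv_iterations = 3, seed = s)
    score_groups(fake_groups(list(g = c("noise1", "noise2"))), m, labs, cfg)$score
  }, numeric(1))
  expect_gt(mean(mean_scores), 0.3)
  expect_lt(mean(mean_scores), 0.7)
})

test_that("scores are invariant to sample order and gene order within a group", {
  sim <- small_sim(seed = 33)
  genes <- sim$truth$modules$genes[[1]]
  labs <- sim$labels
  cfg <- trimint_config(inner_cv_iterations = 3, seed = 17)
  base <- score_groups(fake_groups(list(g = genes)), sim$mrna, labs, cfg)
  rev_genes <- score_groups(fake_groups(list(g = rev(genes))), sim$mrna, labs, cfg)
  expect_equal(base$score, rev_genes$score)
  perm <- withr::with_seed(3, sample(ncol(sim$mrna)))
  shuf <- score_groups(fake_groups(list(g = genes)),
                       om_samples_for_test(sim$mrna, perm), labs, cfg)
  expect_equal(base$score, shuf$score)
})

test_that("stronger class effects never lower the planted group's mean score", {
  effects <- c(0, 1.5, 3)
  means <- vapply(effects, function(eff) {
    mean(vapply(1:8, function(s) {
      sim <- simulate_triomics(n_samples_per_class = 25, n_background = 5,
                               effect_size = eff, seed = 4000 + s)
      cfg <- trimint_config(inner_cv_iterations = 3, seed = s,
                            ttest_p_max = 1)
      score_groups(fake_groups(list(g = sim$truth$modules$genes[[1]])),
                   sim$mrna, sim$labels, cfg)$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > -0.03))
  expect_gt(means[3], means[1] + 0.15)
})

test_that("stratified splits keep both classes and respect the test fraction", {
  y <- factor(rep(c("a", "b"), c(18, 6)))
  for (s in 1:5) {
    sp <- trimint:::stratified_split(y, 1 / 6, seed = s)
    expect_identical(length(sp$test), 4L)  # 3 + 1 by per-class rounding
    expect_setequal(c(sp$train, sp$test), seq_along(y))
    expect_identical(length(unique(y[sp$test])), 2L)
    expect_identical(length(unique(y[sp$train])), 2L)
  }
  inner <- trimint:::make_inner_splits(y, 4, 0.25, seed = 2)
  expect_identical(length(inner), 4L)
  expect_false(identical(inner[[1]]$test, inner[[2]]$test))
})
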
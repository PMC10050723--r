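#' Simulate tri-omics data with planted miRNA-CpG-gene modules
#'
#' Generates matched miRNA, CpG and mRNA matrices over two sample classes
#' under a single-factor Gaussian module model. Each planted module m has a
#' latent factor per sample, `z = effect_size * [class == positive] + N(0, 1)`;
#' its miRNA, CpG and every module gene load on that factor as
#' `loading * z + sqrt(1 - loading^2) * N(0, noise_sd^2)`, with an
#' independently drawn sign for the CpG and each gene (so negative
#' associations, the biologically expected direction for miRNA repression
#' and methylation silencing, occur). Background features are independent
#' standard normals. With `noise_sd = 1` and `effect_size = 0` the population
#' correlation between two features of one module is exactly `loading^2`
#' (see [expected_pair_correlation()]); a positive effect size adds shared
#' class-driven variance and raises it.
#'
#' @param n_samples_per_class samples per class (classes are balanced).
#' @param n_modules number of planted modules.
#' @param genes_per_module planted genes per module.
#' @param n_background background features per omics layer; either one count
#'   or a named vector with names `miRNA`, `CpG`, `mRNA`.
#' @param effect_size difference of latent means between classes, in latent-sd
#'   units.
#' @param loading correlation strength of planted features to their module's
#'   latent factor, in (0, 1].
#' @param noise_sd standard deviation of the feature-specific noise.
#' @param cpg_bounded squash the CpG layer into (0, 1) through a logistic
#'   transform to mimic methylation beta values.
#' @param seed integer seed; the whole fixture is a pure function of it.
#' @param class_labels the two class labels; the second is the positive
#'   (affected) class.
#' @return a `trimint_sim` list: `mirna`, `cpg`, `mrna` ([omics_matrix()]),
#'   `labels` (tibble), and `truth` (planted module definitions: a `modules`
#'   tibble with `module`, `mirna_id`, `cpg_id`, `genes`, plus the latent
#'   factor matrix and the label tibble).
#' @examples
#' sim <- simulate_triomics(n_samples_per_class = 20, n_background = 20, seed = 1)
#' sim$truth$modules
#' @export
simulate_triomics <- function(n_samples_per_class = 60,
                              n_modules = 3,
                              genes_per_module = 5,
                              n_background = c(miRNA = 200, CpG = 200, mRNA = 200),
                              effect_size = 2,
                              loading = 0.8,
                              noise_sd = 1,
                              cpg_bounded = FALSE,
                              seed = 1,
                              class_labels = c("control", "case")) {
  stopifnot(n_samples_per_class >= 2, n_modules >= 1, genes_per_module >= 1,
            effect_size >= 0, loading > 0, loading <= 1, noise_sd >= 0,
            length(class_labels) == 2, class_labels[1] != class_labels[2])
  if (length(n_background) == 1 && is.null(names(n_background))) {
    n_background <- c(miRNA = n_background, CpG = n_background, mRNA = n_background)
  }
  stopifnot(all(c("miRNA", "CpG", "mRNA") %in% names(n_background)))

  n <- 2L * n_samples_per_class
  sample_ids <- sprintf("s%03d", seq_len(n))
  cls <- rep(class_labels, each = n_samples_per_class)
  labels <- tibble::tibble(sample_id = sample_ids, label = cls)
  is_pos <- cls == class_labels[2]

  withr::with_seed(seed, {
    # latent factors: modules x samples
    z <- matrix(stats::rnorm(n_modules * n), n_modules, n)
    z <- z + effect_size * matrix(rep(as.numeric(is_pos), each = n_modules),
                                  n_modules, n)
    planted <- function(module, sign) {
      sign * (loading * z[module, ] +
                sqrt(1 - loading^2) * stats::rnorm(n, sd = noise_sd))
    }
    mk_layer <- function(role, prefix, per_module, signed) {
      rows <- list()
      for (m in seq_len(n_modules)) {
        for (g in seq_len(per_module)) {
          sgn <- if (signed) sample(c(-1, 1), 1) else 1
          id <- if (per_module == 1) sprintf("%s-M%d", prefix, m) else
            sprintf("%s-M%d-%d", prefix, m, g)
          rows[[id]] <- planted(m, sgn)
        }
      }
      nb <- n_background[[role]]
      for (k in seq_len(nb)) {
        rows[[sprintf("%s-bg%04d", prefix, k)]] <- stats::rnorm(n)
      }
      vals <- do.call(rbind, rows)
      colnames(vals) <- sample_ids
      omics_matrix(vals, role = role, name = paste0("sim_", role))
    }
    A <- mk_layer("miRNA", "mir", 1L, signed = FALSE)
    B <- mk_layer("CpG", "cg", 1L, signed = TRUE)
    C <- mk_layer("mRNA", "gene", genes_per_module, signed = TRUE)
  })
  if (cpg_bounded) {
    B <- om_like(stats::plogis(unclass(B)), B)
  }
  modules <- tibble::tibble(
    module = seq_len(n_modules),
    mirna_id = sprintf("mir-M%d", seq_len(n_modules)),
    cpg_id = sprintf("cg-M%d", seq_len(n_modules)),
    genes = lapply(seq_len(n_modules), function(m) {
      if (genes_per_module == 1) sprintf("gene-M%d", m) else
        sprintf("gene-M%d-%d", m, seq_len(genes_per_module))
    })
  )
  structure(list(mirna = A, cpg = B, mrna = C, labels = labels,
                 truth = list(modules = modules, latent = z, labels = labels,
                              positive_label = class_labels[2])),
            class = "trimint_sim")
}

#' @export
print.trimint_sim <- function(x, ...) {
  cat(sprintf("<trimint_sim> %d samples, %d modules; layers: %d miRNA, %d CpG, %d mRNA features\n",
              ncol(x$mirna), nrow(x$truth$modules), nrow(x$mirna), nrow(x$cpg),
              nrow(x$mrna)))
  invisible(x)
}

#' Population correlation of two features sharing one latent factor
#'
#' For two features that both load on the same unit-variance latent factor
#' with equal loading and unit-variance noise, the population Pearson
#' correlation is `loading^2` — the closed form used to place simulation
#' loadings relative to the pairing threshold.
#'
#' @param loading loading in (0, 1].
#' @return `loading^2`.
#' @examples
#' expected_pair_correlation(0.8)
#' @export
expected_pair_correlation <- function(loading) {
  stopifnot(loading > 0, loading <= 1)
  loading^2
}

#' Write a simulated fixture to a directory
#'
#' Writes `A.tsv` (miRNA), `B.tsv` (CpG), `C.tsv` (mRNA), `labels.tsv` and
#' `truth.yaml` into `dir`.
#'
#' @param sim a `trimint_sim` from [simulate_triomics()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_matrix(sim$mirna, file.path(dir, "A.tsv"))
  write_omics_matrix(sim$cpg, file.path(dir, "B.tsv"))
  write_omics_matrix(sim$mrna, file.path(dir, "C.tsv"))
  write_trimint_table(sim$labels, file.path(dir, "labels.tsv"))
  truth <- list(
    positive_label = sim$truth$positive_label,
    modules = purrr::pmap(sim$truth$modules, function(module, mirna_id, cpg_id, genes) {
      list(module = module, mirna_id = mirna_id, cpg_id = cpg_id,
           genes = as.list(genes))
    })
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
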
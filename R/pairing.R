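#' Pearson correlation with a t-transform p-value
#'
#' Sample Pearson coefficient together with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero variance.
#' @return a tibble with columns `r`, `p_value`, `n`.
#' @examples
#' pearson_cor_test(1:4, c(2, 4, 6, 8))
#' @export
pearson_cor_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    rlang::abort("x and y must have equal length >= 3.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Zero-variance vector in correlation.",
                 class = "trimint_zero_variance")
  }
  r <- stats::cor(x, y)
  tibble::tibble(r = r, p_value = cor_p_value(r, length(x)), n = length(x))
}

cor_p_value <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  t <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(-abs(t), n - 2)
  p
}

# All-pairs Pearson matrix between the rows of A and the rows of B via
# standardise-then-crossproduct; rows must be sample-aligned.
cross_correlation <- function(A, B) {
  za <- standardize_rows(A)
  zb <- standardize_rows(B)
  r <- tcrossprod(za, zb) / (ncol(A) - 1)
  r[] <- pmin(1, pmax(-1, r))
  r
}

standardize_rows <- function(m) {
  m <- unclass(m)
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  (m - mu) / s
}

#' Detect correlated miRNA-CpG feature pairs
#'
#' The pairing (P) stage: exhaustively scans all miRNA x CpG feature pairs
#' and keeps every pair whose Pearson correlation satisfies `|r| > alpha`
#' (strict) with two-sided `p < pair_p_max`. Features with zero variance
#' cannot be tested and are skipped with a message. Output is sorted by
#' decreasing `|r|`, then miRNA and CpG ID, so pair lists are reproducible.
#'
#' @param mirna,cpg sample-aligned [omics_matrix()] objects (identical column
#'   order, no missing values).
#' @param alpha correlation threshold in (0, 1].
#' @param pair_p_max p-value gate; `1` disables it.
#' @return a tibble with columns `mirna_id`, `cpg_id`, `r`, `p_value`; the
#'   number of skipped zero-variance features is attached as attribute
#'   `n_zero_variance`.
#' @export
detect_pairs <- function(mirna, cpg, alpha = 0.6, pair_p_max = 0.05) {
  stopifnot(ncol(mirna) == ncol(cpg))
  if (!identical(colnames(mirna), colnames(cpg))) {
    rlang::abort("mirna and cpg must share an identical sample order; run align_samples().")
  }
  if (anyNA(mirna) || anyNA(cpg)) rlang::abort("Missing values must be handled before pairing.")
  n <- ncol(mirna)
  ok_a <- row_sds(mirna) > 0
  ok_b <- row_sds(cpg) > 0
  n_skip <- sum(!ok_a) + sum(!ok_b)
  if (n_skip > 0) {
    message(sprintf("detect_pairs: skipped %d zero-variance features.", n_skip))
  }
  A <- om_features(mirna, which(ok_a))
  B <- om_features(cpg, which(ok_b))
  empty <- tibble::tibble(mirna_id = character(), cpg_id = character(),
                          r = numeric(), p_value = numeric())
  if (nrow(A) == 0 || nrow(B) == 0) {
    warning("detect_pairs: no testable features; returning zero pairs.")
    return(structure(empty, n_zero_variance = n_skip))
  }
  r_mat <- cross_correlation(A, B)
  hit <- which(abs(r_mat) > alpha, arr.ind = TRUE)
  r_hit <- r_mat[hit]
  out <- tibble::tibble(
    mirna_id = rownames(A)[hit[, 1]],
    cpg_id = rownames(B)[hit[, 2]],
    r = r_hit,
    p_value = cor_p_value(r_hit, n)
  )
  out <- dplyr::filter(out, .data$p_value < pair_p_max)
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$r)), .data$mirna_id, .data$cpg_id)
  if (nrow(out) == 0) {
    warning("detect_pairs: no pairs passed the correlation and p-value gates.")
  }
  structure(out, n_zero_variance = n_skip)
}

row_sds <- function(m) {
  m <- unclass(m)
  sqrt(rowSums((m - rowMeans(m))^2) / (ncol(m) - 1))
}
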
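# Independent oracles and tiny fixture builders shared across the suite.
# Every oracle re-derives its quantity from first principles (textbook
# formulas, brute-force loops) and never calls the code path it checks.

make_om <- function(values, role = "mRNA", features = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = length(features))
  rownames(values) <- features %||% sprintf("f%d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  omics_matrix(values, role = role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_class_labels <- function(sample_ids, n_first = length(sample_ids) %/% 2,
                             classes = c("a", "b")) {
  tibble::tibble(sample_id = sample_ids,
                 label = rep(classes, c(n_first, length(sample_ids) - n_first)))
}

# Textbook Pearson r and two-sided p via the t transform.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p = p)
}

# Naive all-pairs scan with the textbook formula.
oracle_pair_scan <- function(A, B, alpha, p_max) {
  out <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      pr <- oracle_pearson(A[i, ], B[j, ])
      if (abs(pr$r) > alpha && pr$p < p_max) {
        out[[length(out) + 1]] <- tibble::tibble(
          mirna_id = rownames(A)[i], cpg_id = rownames(B)[j],
          r = pr$r, p_value = pr$p)
      }
    }
  }
  dplyr::bind_rows(out)
}

# Linear-interpolation quantile from the sorted sample (the type-7 formula,
# written out rather than delegated).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# AUC by brute-force comparison of every positive/negative score pair.
oracle_auc <- function(scores, is_positive) {
  pos <- scores[is_positive]; neg <- scores[!is_positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force average-linkage agglomeration on a symmetric distance matrix.
# Returns the merge history: list of (members_a, members_b, height), with
# cluster member sets kept sorted for comparison.
oracle_average_linkage <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  merges <- list()
  dm <- d
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(dm[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) { best_h <- h; best <- c(i, j) }
      }
    }
    merges[[length(merges) + 1]] <- list(
      a = sort(clusters[[best[1]]]), b = sort(clusters[[best[2]]]),
      height = best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Check that `ord` is a valid leaf order for the oracle's tree: every merged
# cluster occupies a contiguous block of positions.
order_respects_tree <- function(ord, merges) {
  pos <- match(seq_along(ord), ord)
  all(vapply(merges, function(m) {
    idx <- sort(pos[c(m$a, m$b)])
    all(diff(idx) == 1)
  }, logical(1)))
}

# A small deterministic planted fixture used by several module tests.
small_sim <- function(seed = 101, n_per_class = 30, n_bg = 40, ...) {
  simulate_triomics(n_samples_per_class = n_per_class, n_background = n_bg,
                    seed = seed, ...)
}

# Reorder samples of an omics_matrix by position, keeping the class.
om_samples_for_test <- function(m, idx) {
  omics_matrix(unclass(m)[, idx, drop = FALSE], role = omics_role(m))
}

planted_group_names <- function(sim) {
  paste0(sim$truth$modules$mirna_id, "_", sim$truth$modules$cpg_id)
}
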
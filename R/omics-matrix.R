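#' Construct an omics matrix
#'
#' An `omics_matrix` is a numeric feature-by-sample matrix carrying an omics
#' role. Rows are features, columns are samples; both must be uniquely named.
#' Missing values are permitted only for the CpG role (methylation arrays
#' routinely report masked probes), and only before preprocessing.
#'
#' @param values numeric matrix with feature row names and sample column names.
#' @param role one of `"miRNA"`, `"CpG"`, `"mRNA"`.
#' @param name short identifier used in messages and output files.
#' @return an `omics_matrix` (a classed numeric matrix).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("f1", "f2", "f3"), paste0("s", 1:4)))
#' om <- omics_matrix(m, role = "mRNA")
#' omics_role(om)
#' @export
omics_matrix <- function(values, role = c("miRNA", "CpG", "mRNA"), name = NULL) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix.")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  # R stores a zero-length dimnames component as NULL; only a non-empty
  # dimension genuinely lacking names is an error
  if ((is.null(fid) && nrow(values) > 0) || (is.null(sid) && ncol(values) > 0)) {
    rlang::abort("`values` must have feature row names and sample column names.")
  }
  dup_f <- unique(fid[duplicated(fid)])
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_f) > 0) {
    rlang::abort(paste0("Duplicate feature IDs: ", paste(dup_f, collapse = ", ")))
  }
  if (length(dup_s) > 0) {
    rlang::abort(paste0("Duplicate sample IDs: ", paste(dup_s, collapse = ", ")))
  }
  if (role != "CpG" && anyNA(values)) {
    rlang::abort("Missing values are only permitted for role = \"CpG\".")
  }
  if (any(is.infinite(values))) {
    rlang::abort("Non-finite values are not permitted in an omics matrix.")
  }
  structure(values,
            role = role,
            omics_name = name %||% role,
            class = c("omics_matrix", class(matrix())))
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`.
#' @export
omics_role <- function(x) attr(x, "role")

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> role=%s name=%s: %d features x %d samples\n",
              attr(x, "role"), attr(x, "omics_name"), nrow(x), ncol(x)))
  if (nrow(x) > 0 && ncol(x) > 0) {
    print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE], 4L))
  }
  invisible(x)
}

# Rebuild an omics_matrix from new values, inheriting role/name from template.
om_like <- function(values, template) {
  omics_matrix(values, role = attr(template, "role"),
               name = attr(template, "omics_name"))
}

# Subset features/samples while keeping class and attributes.
om_features <- function(x, ids) om_like(unclass(x)[ids, , drop = FALSE], x)
om_samples  <- function(x, ids) om_like(unclass(x)[, ids, drop = FALSE], x)

#' Read a delimited omics matrix
#'
#' Reads a delimited text file with one header row and one leading ID column
#' into an [omics_matrix()]. The delimiter is taken from the file extension
#' (`.csv` is comma, anything else tab) unless given explicitly. Files stored
#' samples-in-rows are transposed into the canonical feature-by-sample
#' orientation.
#'
#' @param path file path.
#' @inheritParams omics_matrix
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param delim optional delimiter override.
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, role = c("miRNA", "CpG", "mRNA"),
                              orientation = c("features_in_rows", "samples_in_rows"),
                              delim = NULL, name = NULL) {
  role <- match.arg(role)
  orientation <- match.arg(orientation)
  delim <- delim %||% guess_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), na = character(), progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2) rlang::abort("Matrix file needs an ID column plus data columns.")
  ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  vals <- parse_numeric_cells(cells, ids, role)
  rownames(vals) <- ids
  m <- tryCatch(
    omics_matrix(vals, role = role, name = name %||% basename(path)),
    error = function(e) rlang::abort(sprintf("In %s: %s", path, conditionMessage(e)))
  )
  if (orientation == "samples_in_rows") {
    m <- om_like(t(unclass(m)), m)
  }
  m
}

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Strict numeric parsing with row/column coordinates in the error. "NA" and
# empty cells are missing markers, legal only for CpG input.
parse_numeric_cells <- function(cells, ids, role) {
  is_missing <- cells == "" | cells == "NA" | cells == "na" | cells == "NaN"
  suppressWarnings(num <- array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is_missing, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    rlang::abort(sprintf(
      "Non-numeric cell '%s' at feature '%s' (row %d), data column %d.",
      cells[b[1], b[2]], ids[b[1]], b[1], b[2]))
  }
  if (any(is_missing) && role != "CpG") {
    b <- which(is_missing, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "Missing value at feature '%s' (row %d), data column %d: only CpG input may contain missing values.",
      ids[b[1]], b[1], b[2]))
  }
  num[is_missing] <- NA_real_
  colnames(num) <- colnames(cells)
  num
}

#' Write an omics matrix to a tab-separated file
#'
#' Writes features in rows with a leading `feature_id` column; numeric values
#' are rendered with 6 significant digits so repeated runs produce
#' byte-identical files.
#'
#' @param x an [omics_matrix()].
#' @param path output path.
#' @export
write_omics_matrix <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), rownames = "feature_id")
  write_trimint_table(df, path)
}

#' Read a sample label table
#'
#' Expects delimited text with a header row and two columns: sample ID and
#' class label. Exactly two distinct labels must be present, each with at
#' least two samples (required for stratified splitting).
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return a tibble with columns `sample_id`, `label`.
#' @export
read_labels <- function(path, delim = NULL) {
  delim <- delim %||% guess_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = "cc",
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2) rlang::abort("Label file needs two columns: sample_id, label.")
  labels <- tibble::tibble(sample_id = df[[1]], label = df[[2]])
  validate_labels(labels)
  labels
}

validate_labels <- function(labels) {
  if (!all(c("sample_id", "label") %in% names(labels))) {
    rlang::abort("`labels` must have columns sample_id and label.")
  }
  if (anyDuplicated(labels$sample_id)) {
    rlang::abort("Duplicate sample IDs in label table.")
  }
  tab <- table(labels$label)
  if (length(tab) != 2) {
    rlang::abort(sprintf("Exactly two classes required, found %d (%s).",
                         length(tab), paste(names(tab), collapse = ", ")))
  }
  if (any(tab < 2)) {
    rlang::abort("Each class needs at least 2 samples for stratified splitting.")
  }
  invisible(labels)
}

#' Restrict omics matrices and labels to their shared samples
#'
#' Intersects the sample IDs of every matrix and the label table and puts all
#' outputs in one canonical (lexicographic, locale-independent) sample order,
#' so that downstream correlation scans see identically aligned columns
#' regardless of input file order.
#'
#' @param matrices a (possibly named) list of [omics_matrix()] objects.
#' @param labels a tibble with columns `sample_id`, `label`.
#' @return a list with elements `matrices` (same shape as input) and `labels`.
#' @export
align_samples <- function(matrices, labels) {
  stopifnot(length(matrices) > 0)
  validate_labels(labels)
  shared <- Reduce(intersect, c(lapply(matrices, colnames), list(labels$sample_id)))
  shared <- sort(shared, method = "radix")
  if (length(shared) < 4) {
    rlang::abort(sprintf(
      "Only %d samples shared across all matrices and labels; need at least 4.",
      length(shared)))
  }
  lab <- labels[match(shared, labels$sample_id), ]
  if (dplyr::n_distinct(lab$label) < 2) {
    rlang::abort("Sample intersection lost one of the two classes entirely.")
  }
  validate_labels(lab)
  list(matrices = lapply(matrices, om_samples, ids = shared), labels = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
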
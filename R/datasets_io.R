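# Reading and writing feature matrices, labels, dissimilarities, embeddings
# and run configurations. Feature matrices are plain numeric matrices with
# sample IDs as rownames and feature IDs as colnames; labels are named
# character vectors.

#' Read a feature matrix from a delimited text file
#'
#' The file must have a header row of feature IDs and a first column of
#' sample IDs. All remaining cells must be numeric; missing or non-numeric
#' values are rejected (the alignment pipeline assumes complete matrices,
#' no imputation is performed).
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, default tab.
#' @return A numeric matrix with `rownames` = sample IDs (file order) and
#'   `colnames` = feature IDs.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tg1\tg2", "s1\t1\t2", "s2\t3\t4"), f)
#' read_feature_matrix(f)
read_feature_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2) stop_bad("'%s' must have an ID column plus >= 1 feature", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop_bad("duplicated sample ID(s) in %s: %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (nrow(df) < 2) stop_bad("'%s' must contain at least 2 samples", path)
  feat <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(feat),
                 dimnames = list(ids, feat))
  for (j in seq_along(feat)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_bad("non-numeric value '%s' at row '%s', column '%s' in %s",
               df[[j + 1L]][bad[1L]], ids[bad[1L]], feat[j], path)
    vals[, j] <- v
  }
  vals
}

#' Write a feature matrix to a delimited text file
#'
#' @param X Numeric matrix with rownames (sample IDs) and colnames.
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @param id_col Name of the ID column in the header.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path, delimiter = "\t", id_col = "sample_id") {
  check_feature_matrix(X)
  df <- data.frame(rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a square dissimilarity matrix
#'
#' Same layout as [read_feature_matrix()]; additionally validated to be
#' square, symmetric, nonnegative with a zero diagonal.
#'
#' @inheritParams read_feature_matrix
#' @return A validated dissimilarity matrix.
#' @export
read_dissimilarity <- function(path, delimiter = "\t") {
  D <- read_feature_matrix(path, delimiter)
  if (nrow(D) != ncol(D))
    stop_bad("'%s' must be square (got %d x %d)", path, nrow(D), ncol(D))
  colnames(D) <- rownames(D)
  check_square_dissimilarity(D, path)
  D
}

#' Read per-sample class labels
#'
#' Expects a two-column delimited file `sample_id, label` with a header.
#'
#' @inheritParams read_feature_matrix
#' @return Named character vector of labels (names = sample IDs).
#' @export
read_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop_bad("label file '%s' needs columns sample_id, label", path)
  if (anyDuplicated(df[[1L]]))
    stop_bad("duplicated sample ID(s) in label file %s", path)
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write per-sample labels
#' @param labels Named character vector (names = sample IDs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict two feature matrices to their shared samples
#'
#' Both outputs contain exactly the intersection of the two sets of sample
#' IDs, sorted lexicographically, so that row i of each output refers to
#' the same sample — the true-match correspondence used by FOSCTTM.
#'
#' @param A,B Numeric matrices with sample IDs as rownames.
#' @return A list with elements `A` and `B`, row-matched.
#' @export
pair_on_shared_samples <- function(A, B) {
  check_feature_matrix(A, "A"); check_feature_matrix(B, "B")
  if (is.null(rownames(A)) || is.null(rownames(B)))
    stop_bad("both matrices need sample IDs as rownames")
  shared <- sort(intersect(rownames(A), rownames(B)))
  if (length(shared) == 0L) stop_bad("no shared sample IDs between A and B")
  list(A = A[shared, , drop = FALSE], B = B[shared, , drop = FALSE])
}

#' Write an embedding to TSV
#'
#' Columns are `sample_id`, `domain`, `dim_1` .. `dim_d`.
#'
#' @param Z Numeric n x d embedding matrix.
#' @param ids Character vector of n sample IDs.
#' @param domain_tag Short string naming the modality/domain.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(Z, ids, domain_tag, path) {
  Z <- as.matrix(Z)
  if (length(ids) != nrow(Z))
    stop_bad("length(ids) = %d does not match nrow(Z) = %d",
             length(ids), nrow(Z))
  df <- data.frame(sample_id = ids, domain = domain_tag, Z,
                   stringsAsFactors = FALSE)
  colnames(df)[-(1:2)] <- paste0("dim_", seq_len(ncol(Z)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path Path to the TSV.
#' @return A list with `Z` (matrix, rownames = sample IDs), `ids`, `domain`.
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  dims <- grep("^dim_", colnames(df))
  Z <- as.matrix(df[, dims, drop = FALSE])
  rownames(Z) <- df$sample_id
  list(Z = Z, ids = df$sample_id, domain = df$domain[1L])
}

#' Default run configuration
#'
#' Central defaults for the alignment pipeline: embedding dimension `d`,
#' matching penalty `lambda`, entropic regularization `eps`, kNN `k`,
#' dissimilarity mode, iteration caps, tolerances, seed and number of
#' repeated runs.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(d = 2L, lambda = 1, eps = 0.01, k = 10L,
       dissimilarity = "geodesic", normalize = TRUE,
       max_outer = 100L, tol_P = 1e-5,
       max_iter = 300L, tol = 1e-6,
       seed = 1L, n_runs = 1L)
}

#' Read a YAML run configuration
#'
#' Keys mirror [default_run_config()]; unknown keys are rejected, missing
#' keys fall back to the defaults, and `overrides` (e.g. CLI flags) take
#' precedence over file values.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file values.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_bad("config file not found: %s", path)
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown))
      stop_bad("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(vals)] <- vals
  }
  cfg[names(overrides)] <- overrides
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$d < 1) stop_bad("d must be >= 1")
  if (cfg$lambda < 0) stop_bad("lambda must be >= 0")
  if (cfg$eps <= 0) stop_bad("eps must be > 0")
  if (cfg$k < 1) stop_bad("k must be >= 1")
  if (cfg$n_runs < 1) stop_bad("n_runs must be >= 1")
  if (!cfg$dissimilarity %in% c("euclidean", "geodesic"))
    stop_bad("dissimilarity must be 'euclidean' or 'geodesic'")
  cfg
}
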
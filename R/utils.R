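# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores the caller's state, so seeded generators are pure functions of
#' their arguments and never perturb the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a small stream index, staying
# within the 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stream) %% 1000L
}

stop_bad <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_square_dissimilarity <- function(D, arg = "D") {
  if (!is.matrix(D) || !is.numeric(D))
    stop_bad("'%s' must be a numeric matrix", arg)
  if (nrow(D) != ncol(D))
    stop_bad("'%s' must be square (got %d x %d)", arg, nrow(D), ncol(D))
  if (any(!is.finite(D)))
    stop_bad("'%s' contains non-finite entries", arg)
  if (any(D < 0))
    stop_bad("'%s' contains negative entries", arg)
  if (max(abs(D - t(D))) > 1e-8)
    stop_bad("'%s' must be symmetric", arg)
  if (any(abs(diag(D)) > 1e-12))
    stop_bad("'%s' must have a zero diagonal", arg)
  invisible(D)
}

check_feature_matrix <- function(X, arg = "X") {
  if (!is.matrix(X) || !is.numeric(X))
    stop_bad("'%s' must be a numeric matrix", arg)
  if (nrow(X) < 2)
    stop_bad("'%s' must have at least 2 samples (rows)", arg)
  if (any(!is.finite(X)))
    stop_bad("'%s' contains non-finite values", arg)
  ids <- rownames(X)
  if (!is.null(ids) && anyDuplicated(ids))
    stop_bad("'%s' has duplicated sample IDs", arg)
  invisible(X)
}
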
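# Preprocessing filters for real feature matrices: zero-variance removal,
# Mann-Whitney U + Bonferroni label-based selection with top-N
# truncation, and variance-to-mean-ratio filtering for unlabelled data.

#' Drop features with zero variance
#'
#' @param F Feature matrix (samples x features).
#' @return Matrix restricted to features with nonzero sample variance.
#' @export
drop_zero_variance <- function(F) {
  check_feature_matrix(F, "F")
  v <- apply(F, 2L, stats::var)
  keep <- v > 0
  if (!any(keep)) stop_bad("all features have zero variance")
  F[, keep, drop = FALSE]
}

# Tie-aware two-sided Mann-Whitney U p-value. Exact enumeration of all
# group assignments when both groups have <= `exact_max` samples (the
# permutation distribution of U is symmetric about n1 n2 / 2 even with
# ties); otherwise the tie-corrected normal approximation with continuity
# correction.
mannwhitney_u_test <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    pooled <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    rr <- rank(pooled)
    Us <- apply(idx, 2L, function(i) sum(rr[i])) - n1 * (n1 + 1) / 2
    mid <- n1 * n2 / 2
    p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-9)
  } else {
    ties <- table(r)
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1))
    z <- (abs(U - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  list(U = U, p = min(1, p))
}

#' Mann-Whitney U feature selection with Bonferroni correction
#'
#' Tests every feature for a two-sided location difference between the
#' two label groups (exact enumeration when both groups have at most 8
#' samples, tie-corrected normal approximation otherwise), applies
#' Bonferroni correction across all tested features, keeps features with
#' corrected p below `alpha`, and truncates to the `top_n` most
#' significant (smallest corrected p, ties broken by raw p then input
#' order).
#'
#' @param F Feature matrix.
#' @param labels Binary label vector/named vector covering the rows of
#'   `F`.
#' @param alpha Significance level on the corrected p-values
#'   (default 0.05).
#' @param top_n Maximum number of surviving features (default `Inf`).
#' @return List with `matrix` (the selected columns of `F`) and `report`
#'   (data.frame: `feature_id`, `U`, `p`, `p_adj`, `selected`).
#' @export
mannwhitney_select <- function(F, labels, alpha = 0.05, top_n = Inf) {
  check_feature_matrix(F, "F")
  if (!is.null(names(labels)) && !is.null(rownames(F)))
    labels <- labels[rownames(F)]
  labels <- as.character(labels)
  if (length(labels) != nrow(F) || anyNA(labels))
    stop_bad("labels must cover every sample of F")
  groups <- sort(unique(labels))
  if (length(groups) != 2L)
    stop_bad("Mann-Whitney selection needs exactly 2 label groups, got %d",
             length(groups))
  g1 <- labels == groups[1L]
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stop_bad("each label group needs at least 2 samples")
  tests <- lapply(seq_len(ncol(F)), function(j)
    mannwhitney_u_test(F[g1, j], F[!g1, j]))
  m <- ncol(F)
  p_raw <- vapply(tests, `[[`, numeric(1), "p")
  report <- data.frame(
    feature_id = colnames(F) %||% as.character(seq_len(m)),
    U = vapply(tests, `[[`, numeric(1), "U"),
    p = p_raw,
    p_adj = stats::p.adjust(p_raw, method = "bonferroni"),
    stringsAsFactors = FALSE)
  sig <- which(report$p_adj < alpha)
  if (length(sig) > top_n) {
    ord <- sig[order(report$p_adj[sig], report$p[sig], sig)]
    sig <- sort(ord[seq_len(top_n)])
  }
  report$selected <- seq_len(m) %in% sig
  list(matrix = F[, sig, drop = FALSE], report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance-to-mean ratio filter
#'
#' Keeps features whose unbiased sample variance divided by their mean
#' exceeds `threshold`; the label-free filter used when class labels are
#' incomplete. The ratio is undefined for non-positive means, so such
#' features are dropped with a warning.
#'
#' @param F Feature matrix.
#' @param threshold Ratio cutoff (default 0.01).
#' @return Matrix of surviving features.
#' @export
variance_mean_ratio_filter <- function(F, threshold = 0.01) {
  check_feature_matrix(F, "F")
  mu <- colMeans(F)
  v <- apply(F, 2L, stats::var)
  nonpos <- mu <= 0
  if (any(nonpos))
    warning(sprintf(
      "dropping %d feature(s) with non-positive mean (ratio undefined)",
      sum(nonpos)), call. = FALSE)
  keep <- !nonpos & (v / mu > threshold)
  if (!any(keep)) stop_bad("no features survive the variance-to-mean filter")
  F[, keep, drop = FALSE]
}
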
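# Alignment quality metrics: FOSCTTM (fraction of samples closer than the
# true match) and k-NN label transfer accuracy, with repeated-seed
# aggregation and pairwise averaging for three-domain runs.

#' FOSCTTM: fraction of samples closer than the true match
#'
#' Row i of `Z` and row i of `Zp` must refer to the same sample. For each
#' sample the fraction of the other domain's samples lying *strictly*
#' closer than its true counterpart is computed; the score averages over
#' all samples in both directions. 0 means perfect alignment; a random
#' alignment scores about 0.5. Ties (equal distances) do not count
#' against the match.
#'
#' @param Z,Zp Embeddings with equal row counts, rows matched.
#' @return Fraction in `[0, 1]`.
#' @export
foscttm <- function(Z, Zp) {
  Z <- as.matrix(Z); Zp <- as.matrix(Zp)
  n <- nrow(Z)
  if (nrow(Zp) != n)
    stop_bad("FOSCTTM needs equal sample counts (got %d and %d)", n, nrow(Zp))
  Cd <- outer(rowSums(Z^2), rowSums(Zp^2), "+") - 2 * tcrossprod(Z, Zp)
  tm <- diag(Cd)
  # direction 1: for each i, other-domain samples j != i closer than match
  f1 <- (rowSums(Cd < tm) - 0) / (n - 1)        # Cd[i,i] < tm[i] is FALSE
  f2 <- (colSums(Cd < rep(tm, each = n))) / (n - 1)
  mean(c(f1, f2))
}

#' k-NN label transfer accuracy
#'
#' Trains a k-nearest-neighbour majority-vote classifier on one domain's
#' embedding and labels, predicts the other domain's labels, and returns
#' the fraction correct. Neighbour ties at equal distance resolve to the
#' smaller training index; vote ties resolve to the lexicographically
#' smallest label. Both embeddings must live in the same aligned frame.
#'
#' @param Z_train,Z_test Embeddings in the common frame.
#' @param labels_train,labels_test Label vectors (coerced to character).
#' @param k Number of neighbours (default 5).
#' @return Fraction of correctly predicted test labels.
#' @export
label_transfer_accuracy <- function(Z_train, labels_train, Z_test,
                                    labels_test, k = 5L) {
  Z_train <- as.matrix(Z_train); Z_test <- as.matrix(Z_test)
  n_train <- nrow(Z_train)
  if (k > n_train)
    stop_bad("k = %d exceeds the number of training samples (%d)", k, n_train)
  if (length(labels_train) != n_train ||
      length(labels_test) != nrow(Z_test))
    stop_bad("label lengths do not match embedding rows")
  labels_train <- as.character(labels_train)
  labels_test <- as.character(labels_test)
  Cd <- outer(rowSums(Z_test^2), rowSums(Z_train^2), "+") -
    2 * tcrossprod(Z_test, Z_train)
  pred <- vapply(seq_len(nrow(Z_test)), function(i) {
    nb <- order(Cd[i, ])[seq_len(k)]     # stable: index breaks ties
    votes <- sort(table(labels_train[nb]), decreasing = TRUE)
    top <- names(votes)[votes == votes[1L]]
    sort(top)[1L]
  }, character(1))
  mean(pred == labels_test)
}

#' Evaluate a three-domain alignment
#'
#' Computes FOSCTTM and label transfer accuracy on the three pairs of
#' final embeddings — (Z1, Z2), (Z1, Z3), (Z2, Z3) — and reports the
#' per-pair values and their averages as the overall performance scores.
#'
#' @param result A [joint_mds3()] result (or any list with `Z1`, `Z2`,
#'   `Z3`).
#' @param labels Label vector covering all samples (one per row).
#' @param k Neighbours for the transfer classifier (default 5).
#' @param direction Transfer direction per pair: train on the first
#'   domain of the pair (`"1to2"`, default), the second (`"2to1"`), or
#'   average both (`"both"`).
#' @return List with `pairs` (data.frame of per-pair scores), `foscttm`
#'   and `transfer_accuracy` (the averages).
#' @export
evaluate_tri <- function(result, labels, k = 5L,
                         direction = c("1to2", "2to1", "both")) {
  direction <- match.arg(direction)
  Zs <- list(result$Z1, result$Z2, result$Z3)
  n <- nrow(Zs[[1L]])
  if (length(labels) != n)
    stop_bad("labels must cover all %d samples (got %d)", n, length(labels))
  idx <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  rows <- lapply(idx, function(p) {
    Za <- Zs[[p[1L]]]; Zb <- Zs[[p[2L]]]
    acc <- switch(direction,
      "1to2" = label_transfer_accuracy(Za, labels, Zb, labels, k),
      "2to1" = label_transfer_accuracy(Zb, labels, Za, labels, k),
      "both" = mean(c(label_transfer_accuracy(Za, labels, Zb, labels, k),
                      label_transfer_accuracy(Zb, labels, Za, labels, k))))
    data.frame(pair = paste0("Z", p[1L], "-Z", p[2L]),
               foscttm = foscttm(Za, Zb), transfer_accuracy = acc)
  })
  pairs <- do.call(rbind, rows)
  list(pairs = pairs,
       foscttm = mean(pairs$foscttm),
       transfer_accuracy = mean(pairs$transfer_accuracy))
}

#' Repeated runs over seeds
#'
#' Runs an alignment/evaluation function for `n_runs` consecutive seeds
#' (`base_seed .. base_seed + n_runs - 1`) and aggregates each returned
#' metric by its mean and population standard deviation.
#'
#' @param run_fn Function of a single integer seed returning a named
#'   numeric vector (or list) of metrics.
#' @param n_runs Number of runs (default 50).
#' @param base_seed First seed.
#' @return List with `per_seed` (data.frame, one row per seed), `mean`
#'   and `sd` (named vectors; `sd` is the population standard deviation),
#'   and `n_runs`.
#' @export
repeated_runs <- function(run_fn, n_runs = 50L, base_seed = 0L) {
  if (n_runs < 1) stop_bad("n_runs must be >= 1")
  seeds <- base_seed + seq_len(n_runs) - 1L
  vals <- lapply(seeds, function(s) unlist(run_fn(s)))
  per_seed <- as.data.frame(do.call(rbind, vals))
  per_seed <- cbind(seed = seeds, per_seed)
  m <- colMeans(per_seed[, -1L, drop = FALSE])
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  s <- vapply(per_seed[, -1L, drop = FALSE], pop_sd, numeric(1))
  list(per_seed = per_seed, mean = m, sd = s, n_runs = n_runs)
}
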
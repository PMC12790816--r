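# Weighted multidimensional scaling by SMACOF stress majorization, and the
# stacked-configuration joint step that couples two domains through a
# transport plan inside the joint alignment objective.
#
# Stress is summed over ordered pairs i != j with a symmetric weight
# matrix (equivalently twice the i < j sum); one convention is used
# everywhere so stress values, majorization bounds and the joint objective
# are mutually consistent.

#' Random initial embedding
#'
#' @param n Number of points.
#' @param d Embedding dimension.
#' @param seed Integer seed; the same seed yields the identical matrix.
#' @return n x d matrix of i.i.d. standard normal coordinates.
#' @export
init_embedding <- function(n, d, seed) {
  if (n < 1 || d < 1) stop_bad("n and d must be >= 1")
  local_seed(seed, matrix(stats::rnorm(n * d), n, d))
}

#' Uniform MDS weight matrix
#'
#' The default weighting `1/n^2` for every off-diagonal pair.
#'
#' @param n Number of points.
#' @return n x n matrix with `1/n^2` off the diagonal, zero diagonal.
#' @export
uniform_weights <- function(n) {
  W <- matrix(1 / n^2, n, n)
  diag(W) <- 0
  W
}

#' Weighted MDS stress
#'
#' `sum_{i != j} w_ij (d_ij - |z_i - z_j|)^2` for a symmetric weight
#' matrix `W` with zero diagonal.
#'
#' @param Z n x d embedding.
#' @param D n x n target dissimilarity matrix.
#' @param W n x n symmetric weight matrix (default uniform `1/n^2`).
#' @return Nonnegative scalar.
#' @export
mds_stress <- function(Z, D, W = uniform_weights(nrow(D))) {
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(D) || any(dim(D) != dim(W)))
    stop_bad("shape mismatch between Z (%d), D (%d x %d) and W (%d x %d)",
             nrow(Z), nrow(D), ncol(D), nrow(W), ncol(W))
  E <- fast_dist(Z)
  sum(W * (D - E)^2)
}

# Euclidean distance matrix, avoiding the dist() round trip.
fast_dist <- function(X) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  E <- -2 * tcrossprod(X)
  E <- E + sq                  # adds sq_i down each column
  E <- E + rep(sq, each = n)   # adds sq_j across each row
  E[E < 0] <- 0
  sqrt(E)
}

# V matrix of the Guttman transform: V = diag(rowSums(W)) - W.
guttman_v <- function(W) {
  V <- -W
  diag(V) <- rowSums(W)
  V
}

# Pseudoinverse of V. When the weight graph is connected the nullspace of
# V is span(1) and the de Leeuw identity V+ = (V + 11')^{-1} - 11'/n^2
# applies; otherwise fall back to a full Moore-Penrose pseudoinverse.
guttman_vinv <- function(W) {
  n <- nrow(W)
  Wo <- W
  diag(Wo) <- Inf
  connected <- all(Wo > 0) || weight_graph_connected(W)
  V <- guttman_v(W)
  if (connected) {
    solve(V + 1) - 1 / n^2
  } else {
    MASS::ginv(V)
  }
}

# Breadth-first reachability on the positive-weight graph.
weight_graph_connected <- function(W) {
  n <- nrow(W)
  A <- (W > 0) | (t(W) > 0)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# Iterated Guttman transforms with a single distance evaluation per step.
# `WD` is the precomputed elementwise product W * D; `unif_w` is the
# off-diagonal weight when W is uniform (NULL otherwise, requiring
# `Vinv`). Returns the updated configuration and the stress trace
# (stress before each accepted update, plus the final stress).
smacof_engine <- function(X, D, W, WD, Vinv = NULL, unif_w = NULL,
                          max_steps = 100L, tol = 1e-6) {
  n <- nrow(X)
  trace <- numeric(0)
  for (step in seq_len(max_steps)) {
    E <- fast_dist(X)
    st <- sum(W * (D - E)^2)
    trace <- c(trace, st)
    if (step > 1L) {
      prev <- trace[step - 1L]
      if (prev <= 0 || (prev - st) / prev < tol) break
    }
    Ez <- E
    Ez[Ez == 0] <- Inf           # coincident pairs contribute zero
    B <- WD / Ez
    rs <- rowSums(B)
    B <- -B
    diag(B) <- rs
    BX <- B %*% X
    X <- if (!is.null(unif_w)) BX / (n * unif_w) else Vinv %*% BX
  }
  E <- fast_dist(X)
  trace <- c(trace, sum(W * (D - E)^2))
  list(X = X, trace = trace)
}

#' One SMACOF majorization step
#'
#' The Guttman transform: `Z_new = V^+ B(Z) Z`, which never increases the
#' stress. Pairs of coincident points (embedded distance 0) contribute
#' zero to `B`, the standard guard against division by zero.
#'
#' @inheritParams mds_stress
#' @param Vinv Optional precomputed pseudoinverse of the Guttman `V`
#'   matrix for non-uniform weights; for uniform weights the closed form
#'   `B(Z) Z / (n w)` is used automatically.
#' @return Updated embedding with `mds_stress(new) <= mds_stress(old)`.
#' @export
smacof_step <- function(Z, D, W = uniform_weights(nrow(D)), Vinv = NULL) {
  Z <- as.matrix(Z)
  E <- fast_dist(Z)
  R <- matrix(0, nrow(D), ncol(D))
  pos <- E > 0
  R[pos] <- (W * D)[pos] / E[pos]
  B <- -R
  diag(B) <- rowSums(R)
  BZ <- B %*% Z
  if (is.null(Vinv)) {
    w <- W[1L, 2L]
    if (is_uniform_weights(W, w)) {
      # V+ B Z = B Z / (n w): B has zero row/col sums so the centering
      # projector in V+ acts as the identity on B Z
      return(BZ / (nrow(D) * w))
    }
    Vinv <- guttman_vinv(W)
  }
  Vinv %*% BZ
}

is_uniform_weights <- function(W, w = W[1L, 2L]) {
  if (w <= 0) return(FALSE)
  Wo <- W
  diag(Wo) <- w
  max(abs(Wo - w)) < 1e-15
}

#' Weighted MDS by SMACOF
#'
#' Iterates [smacof_step()] until the relative stress decrease falls below
#' `tol` or `max_iter` steps have been taken.
#'
#' @inheritParams mds_stress
#' @param d Embedding dimension (used only to validate `init`).
#' @param init Initial n x d embedding, e.g. from [init_embedding()].
#' @param max_iter Maximum number of majorization steps.
#' @param tol Relative stress-change convergence tolerance.
#' @return List with `embedding` (n x d matrix) and `trace`
#'   (non-increasing vector of stress values, starting at the stress of
#'   `init`).
#' @export
weighted_mds <- function(D, W = uniform_weights(nrow(D)), d = 2L,
                         init = NULL, max_iter = 300L, tol = 1e-6) {
  check_square_dissimilarity(D)
  n <- nrow(D)
  if (is.null(init)) init <- init_embedding(n, d, seed = 0L)
  Z <- as.matrix(init)
  if (ncol(Z) != d)
    stop_bad("init has %d columns but d = %d", ncol(Z), d)
  if (max_iter == 0L)
    return(list(embedding = Z, trace = mds_stress(Z, D, W),
                iterations = 0L))
  unif <- is_uniform_weights(W)
  eng <- smacof_engine(Z, D, W, WD = W * D,
                       Vinv = if (unif) NULL else guttman_vinv(W),
                       unif_w = if (unif) W[1L, 2L] else NULL,
                       max_steps = max_iter, tol = tol)
  list(embedding = eng$X, trace = eng$trace,
       iterations = length(eng$trace) - 1L)
}

#' Joint objective of the two-domain alignment
#'
#' `stress(Z, D, W) + stress(Z', D', W') + 2 lambda <P, d^2(Z O, Z')>_F`:
#' within-domain stress plus the transport-weighted squared cross-domain
#' distances under the orthogonal map `O`.
#'
#' @param Z,Zp Embeddings of the two domains (n x d, n' x d).
#' @param D,Dp Dissimilarity matrices.
#' @param W,Wp Weight matrices.
#' @param P n x n' coupling (transport plan).
#' @param O d x d orthogonal transform applied to `Z`.
#' @param lambda Nonnegative matching penalty.
#' @return Scalar objective value.
#' @export
joint_objective <- function(Z, Zp, D, Dp, W, Wp, P, O, lambda) {
  mds_stress(Z, D, W) + mds_stress(Zp, Dp, Wp) +
    2 * lambda * sum(P * squared_distance_cost(Z, O, Zp))
}

#' One majorization step on the coupled two-domain configuration
#'
#' The coupling term `2 lambda sum_ij P_ij |z_i O - z'_j|^2` is absorbed
#' into a single weighted-MDS problem on the stacked `(n + n')`-point
#' configuration `[Z O ; Z']` with block dissimilarities
#' `[[D, 0], [0, D']]` and block weights `[[W, lambda P], [lambda P', W']]`
#' (cross-pairs have target dissimilarity 0, i.e. matched samples are
#' pulled together). One SMACOF step on that problem never increases the
#' joint objective. With `lambda = 0` the update reduces to two
#' independent [smacof_step()]s.
#'
#' @inheritParams joint_objective
#' @param Vinv Optional precomputed pseudoinverse of the stacked Guttman
#'   `V` matrix (reusable while `P` and `lambda` are fixed).
#' @return List with updated `Z` (in its own frame) and `Zp`.
#' @export
joint_stress_step <- function(Z, Zp, D, Dp, W, Wp, P, O, lambda,
                              Vinv = NULL) {
  if (lambda < 0) stop_bad("lambda must be >= 0")
  if (lambda == 0) {
    return(list(Z = smacof_step(Z, D, W), Zp = smacof_step(Zp, Dp, Wp)))
  }
  n <- nrow(D); np <- nrow(Dp)
  Dblk <- rbind(cbind(D, matrix(0, n, np)), cbind(matrix(0, np, n), Dp))
  Wblk <- rbind(cbind(W, lambda * P), cbind(lambda * t(P), Wp))
  X <- rbind(Z %*% O, Zp)
  if (is.null(Vinv)) Vinv <- guttman_vinv(Wblk)
  Xn <- smacof_step(X, Dblk, Wblk, Vinv = Vinv)
  list(Z = Xn[seq_len(n), , drop = FALSE] %*% t(O),
       Zp = Xn[n + seq_len(np), , drop = FALSE])
}

# Precompute the stacked block weight pseudoinverse for repeated
# joint_stress_step calls with fixed P and lambda.
joint_vinv <- function(W, Wp, P, lambda) {
  n <- nrow(W); np <- nrow(Wp)
  Wblk <- rbind(cbind(W, lambda * P), cbind(lambda * t(P), Wp))
  guttman_vinv(Wblk)
}
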
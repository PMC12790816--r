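# Labelled synthetic manifold benchmarks: a bifurcating trajectory, the
# Swiss roll, and a circular frustum, each drawn in 2-3 intrinsic
# dimensions, linearly projected into high-dimensional feature spaces
# with Gaussian noise, plus a third domain constructed from principal
# components of the combined pair. Every generator is a pure function of
# its parameters and seed.

#' Draw a labelled synthetic manifold
#'
#' * `bifurcation`: a planar trajectory whose trunk splits into two noisy
#'   branches; labels 1 (trunk), 2 and 3 (branches).
#' * `swiss_roll`: the classic 3-D roll `(t cos t, h, t sin t)`; labels
#'   are three contiguous bands of the roll parameter `t`.
#' * `circular_frustum`: points on a truncated-cone surface; labels are
#'   three angular sectors.
#'
#' @param kind One of `"bifurcation"`, `"swiss_roll"`,
#'   `"circular_frustum"`.
#' @param n Number of samples (default 300).
#' @param seed Integer seed.
#' @return List of class `manifold_sample` with `coords` (n x q matrix,
#'   q = 2 or 3, rownames = sample IDs), `labels` (named character
#'   vector in `{"1","2","3"}`) and `kind`.
#' @export
make_manifold <- function(kind = c("bifurcation", "swiss_roll",
                                   "circular_frustum"),
                          n = 300L, seed = 0L) {
  kind <- match.arg(kind)
  if (n < 3) stop_bad("n must be >= 3")
  out <- local_seed(seed, switch(kind,
    bifurcation = {
      t <- stats::runif(n)
      branch <- ifelse(t < 0.5, 1L, sample(2:3, n, replace = TRUE))
      # the two branches are deliberately geometrically distinct (a
      # straight arm and a curved, shallower arm): exactly
      # mirror-symmetric branches would make the unsupervised
      # correspondence ill-posed
      s <- t - 0.5
      y <- ifelse(branch == 1L, 0,
                  ifelse(branch == 2L, 1.5 * s, -0.9 * s - 2.4 * s^2))
      coords <- cbind(t, y) + matrix(stats::rnorm(2 * n, sd = 0.02), n, 2)
      list(coords = coords, labels = branch)
    },
    swiss_roll = {
      u <- stats::runif(n)
      t <- 1.5 * pi * (1 + 2 * u)
      h <- stats::runif(n, 0, 21)
      coords <- cbind(t * cos(t), h, t * sin(t))
      list(coords = coords, labels = cut(u, c(0, 1 / 3, 2 / 3, 1),
                                         labels = FALSE,
                                         include.lowest = TRUE))
    },
    circular_frustum = {
      theta <- stats::runif(n, 0, 2 * pi)
      z <- stats::runif(n)
      r <- 1 - 0.5 * z
      coords <- cbind(r * cos(theta), r * sin(theta), z)
      list(coords = coords, labels = findInterval(theta, 2 * pi * (1:2) / 3) + 1L)
    }))
  ids <- sprintf("s%04d", seq_len(n))
  coords <- unname(out$coords)
  rownames(coords) <- ids
  structure(list(coords = coords,
                 labels = stats::setNames(as.character(out$labels), ids),
                 kind = kind),
            class = "manifold_sample")
}

#' Linearly project a manifold into a high-dimensional feature space
#'
#' Multiplies the intrinsic coordinates by a random Gaussian projection
#' matrix (entries `N(0, 1/q)`, variance preserving) and adds i.i.d.
#' Gaussian noise.
#'
#' @param M A `manifold_sample` (or plain coordinate matrix).
#' @param target_dim Output dimensionality, `>= q`.
#' @param noise_sd Standard deviation of the additive noise.
#' @param seed Integer seed.
#' @return n x `target_dim` feature matrix (rownames = sample IDs).
#' @export
project_domain <- function(M, target_dim, noise_sd = 0.05, seed = 0L) {
  coords <- if (inherits(M, "manifold_sample")) M$coords else as.matrix(M)
  q <- ncol(coords)
  n <- nrow(coords)
  if (target_dim < q)
    stop_bad("target_dim = %d below intrinsic dimension q = %d",
             target_dim, q)
  X <- local_seed(seed, {
    G <- matrix(stats::rnorm(q * target_dim, sd = 1 / sqrt(q)), q, target_dim)
    coords %*% G +
      if (noise_sd > 0) matrix(stats::rnorm(n * target_dim, sd = noise_sd),
                               n, target_dim) else 0
  })
  rownames(X) <- rownames(coords)
  colnames(X) <- sprintf("f%04d", seq_len(target_dim))
  X
}

#' Construct the third synthetic domain from a projected pair
#'
#' Column-concatenates the two domains (same samples), computes the
#' leading `dim` principal-component loadings of the combined matrix,
#' maps domain 1 through the domain-1 block of those loadings, and adds
#' i.i.d. Gaussian noise. When `dim` exceeds the sample rank of the
#' combined matrix, the remaining loadings are LAPACK's orthonormal
#' completion of the right singular vectors (zero-variance directions),
#' which keeps the construction defined for any `dim` up to the total
#' feature count.
#'
#' @param F1,F2 Feature matrices sharing sample IDs and order.
#' @param dim Output dimensionality (default 500).
#' @param noise_sd Standard deviation of the additive noise
#'   (default 0.05).
#' @param seed Integer seed.
#' @return n x `dim` feature matrix; with `noise_sd = 0` an exact linear
#'   function of `F1`.
#' @export
make_third_domain <- function(F1, F2, dim = 500L, noise_sd = 0.05,
                              seed = 0L) {
  check_feature_matrix(F1, "F1"); check_feature_matrix(F2, "F2")
  if (!identical(rownames(F1), rownames(F2)))
    stop_bad("F1 and F2 must share sample IDs in identical order")
  comb <- cbind(F1, F2)
  if (dim > ncol(comb))
    stop_bad("dim = %d exceeds the combined feature count %d", dim, ncol(comb))
  ctr <- scale(comb, center = TRUE, scale = FALSE)
  V <- svd(ctr, nu = 0L, nv = dim)$v          # combined-space loadings
  L1 <- V[seq_len(ncol(F1)), , drop = FALSE]  # domain-1 block
  X <- F1 %*% L1
  if (noise_sd > 0)
    X <- X + local_seed(seed, matrix(stats::rnorm(length(X), sd = noise_sd),
                                     nrow(X), ncol(X)))
  rownames(X) <- rownames(F1)
  colnames(X) <- sprintf("pc%04d", seq_len(dim))
  X
}

#' Generate a full synthetic three-domain benchmark triplet
#'
#' One manifold draw projected to 1000 and 2000 dimensions (domains 1 and
#' 2) plus the 500-dimensional third domain built from principal
#' components of the combined pair applied to domain 1, all sharing
#' sample IDs and labels.
#'
#' @param kind Manifold kind, see [make_manifold()].
#' @param n Samples per domain (default 300).
#' @param seed Integer seed driving every random draw.
#' @param dims Target dimensionalities of the three domains.
#' @param noise_sd Additive noise standard deviation for all domains.
#' @return List with `domains` (list of three feature matrices), `labels`
#'   (named character vector) and `manifold`.
#' @export
make_triplet <- function(kind, n = 300L, seed = 0L,
                         dims = c(1000L, 2000L, 500L), noise_sd = 0.05) {
  M <- make_manifold(kind, n = n, seed = derive_seed(seed, 1L))
  F1 <- project_domain(M, dims[1L], noise_sd, seed = derive_seed(seed, 2L))
  F2 <- project_domain(M, dims[2L], noise_sd, seed = derive_seed(seed, 3L))
  F3 <- make_third_domain(F1, F2, dim = dims[3L], noise_sd = noise_sd,
                          seed = derive_seed(seed, 4L))
  list(domains = list(F1, F2, F3), labels = M$labels, manifold = M)
}
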
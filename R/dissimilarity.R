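# Per-modality dissimilarity construction: Euclidean distances, k-nearest
# neighbour graphs and geodesic (shortest-path) distances approximating
# distances along the data manifold.

#' Pairwise Euclidean dissimilarity matrix
#'
#' @param X Numeric samples x features matrix.
#' @return Symmetric n x n matrix of L2 distances, zero diagonal; rownames
#'   and colnames carry the sample IDs of `X`.
#' @export
pairwise_euclidean <- function(X) {
  check_feature_matrix(X)
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' k-nearest neighbour graph from a dissimilarity matrix
#'
#' Each sample is connected to its `k` nearest others (ties broken by the
#' smaller sample index) and the edge set is union-symmetrized: an edge is
#' kept whenever either endpoint selects it, the standard Isomap
#' construction. Edge weights are the input dissimilarities.
#'
#' @param D Square dissimilarity matrix.
#' @param k Number of neighbours, `1 <= k <= n - 1`.
#' @return An undirected weighted [igraph::graph] with `n` vertices.
#' @export
knn_graph <- function(D, k) {
  check_square_dissimilarity(D)
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 1L || k > n - 1L)
    stop_bad("k must be in [1, n-1] = [1, %d], got %d", n - 1L, k)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    # order() is stable: equidistant neighbours resolve to the lower index
    nb <- order(d)[seq_len(k)]
    edges[[i]] <- cbind(i, nb)
  }
  e <- do.call(rbind, edges)
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- D[e]
  g
}

#' Geodesic distances along a k-nearest neighbour graph
#'
#' All-pairs shortest-path distances on [knn_graph()], the sum of edge
#' weights along the shortest path connecting two samples. If the graph is
#' disconnected, the two closest samples (by input dissimilarity) of each
#' pair of components are joined, with a warning, until the graph is
#' connected — no sample is ever dropped.
#'
#' @inheritParams knn_graph
#' @return Symmetric matrix of geodesic distances, entrywise no smaller
#'   than `D` when `D` satisfies the triangle inequality.
#' @export
geodesic_distances <- function(D, k) {
  g <- knn_graph(D, k)
  n <- nrow(D)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning(sprintf(
      "kNN graph (k = %d) has %d components; bridging closest pairs",
      as.integer(k), comp$no), call. = FALSE)
    while (comp$no > 1L) {
      # join the globally closest pair of samples in different components
      m <- comp$membership
      cross <- outer(m, m, "!=")
      Dc <- D
      Dc[!cross] <- Inf
      idx <- arrayInd(which.min(Dc), dim(Dc))
      g <- igraph::add_edges(g, c(idx[1L], idx[2L]),
                             weight = D[idx[1L], idx[2L]])
      comp <- igraph::components(g)
    }
  }
  G <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(G) <- dimnames(D)
  diag(G) <- 0
  (G + t(G)) / 2
}

#' Max-normalize a dissimilarity matrix
#'
#' Divides by the largest entry so that dissimilarities lie in `[0, 1]`,
#' making stress contributions comparable across modalities with
#' incomparable raw scales.
#'
#' @param D Square dissimilarity matrix with `max(D) > 0`.
#' @return Rescaled matrix with maximum entry 1.
#' @export
normalize_dissimilarity <- function(D) {
  check_square_dissimilarity(D)
  m <- max(D)
  if (m <= 0) stop_bad("cannot normalize an all-zero dissimilarity matrix")
  D / m
}

#' Dissimilarity matrix for one modality
#'
#' Convenience wrapper chaining [pairwise_euclidean()], optionally
#' [geodesic_distances()], and [normalize_dissimilarity()].
#'
#' @param X Feature matrix.
#' @param mode `"euclidean"` or `"geodesic"`.
#' @param k Neighbours for the geodesic graph (ignored for Euclidean).
#' @param normalize Max-normalize the result (default `TRUE`).
#' @return Dissimilarity matrix.
#' @export
modality_dissimilarity <- function(X, mode = c("geodesic", "euclidean"),
                                   k = 10L, normalize = TRUE) {
  mode <- match.arg(mode)
  D <- pairwise_euclidean(X)
  if (mode == "geodesic") D <- geodesic_distances(D, k)
  if (normalize) D <- normalize_dissimilarity(D)
  D
}
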
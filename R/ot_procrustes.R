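# Entropic optimal transport (stabilized Sinkhorn scaling) and orthogonal
# Procrustes, alternated as the Wasserstein-Procrustes matching between two
# embeddings.

#' Squared-distance cost matrix between two embeddings
#'
#' `C[i, j] = |z_i O - z'_j|^2` for the orthogonal map `O` applied to the
#' first embedding.
#'
#' @param Z n x d embedding.
#' @param O d x d orthogonal matrix.
#' @param Zp n' x d embedding.
#' @return n x n' nonnegative cost matrix.
#' @export
squared_distance_cost <- function(Z, O, Zp) {
  Z <- as.matrix(Z); Zp <- as.matrix(Zp)
  if (ncol(Z) != ncol(O) || nrow(O) != ncol(O) || ncol(Zp) != ncol(O))
    stop_bad("dimension mismatch: Z is n x %d, O is %d x %d, Z' is n' x %d",
             ncol(Z), nrow(O), ncol(O), ncol(Zp))
  A <- Z %*% O
  C <- outer(rowSums(A^2), rowSums(Zp^2), "+") - 2 * tcrossprod(A, Zp)
  C[C < 0] <- 0
  C
}

#' Entropy of a coupling
#'
#' `H(P) = -sum_ij P_ij (log P_ij - 1)` with the convention
#' `0 log 0 = 0`. Under this form the Sinkhorn scaling fixed point is the
#' exact optimum of the entropic objective `<P, C> - eps H(P)`.
#'
#' @param P Nonnegative coupling matrix.
#' @return Scalar entropy.
#' @export
coupling_entropy <- function(P) {
  p <- P[P > 0]
  -sum(p * (log(p) - 1))
}

#' Entropic optimal transport by stabilized Sinkhorn scaling
#'
#' Solves `min_{P in Pi(a, b)} <P, C>_F - eps H(P)` by diagonal matrix
#' scaling, `P = diag(u) exp(-C / eps) diag(v)`, with log-domain
#' absorption of large scaling factors so that small `eps` does not
#' overflow. Fully deterministic.
#'
#' @param C n x n' cost matrix (finite, nonnegative).
#' @param a,b Positive marginals summing to 1 (defaults: uniform).
#' @param eps Entropic regularization, `> 0`.
#' @param max_iter Maximum scaling iterations.
#' @param tol Maximum absolute marginal residual required for convergence.
#' @param potentials Optional list `(f, g)` of warm-start dual potentials.
#' @param anneal Use an epsilon-scaling warm-up schedule when no
#'   potentials are supplied (recommended for small `eps`).
#' @param on_fail What to do when the residual still exceeds `tol` after
#'   `max_iter` iterations: `"error"` (default), or `"round"` — project
#'   the plan onto the exact marginal polytope by row/column rescaling
#'   plus a rank-one correction, keeping the reported `residual` as the
#'   pre-projection value.
#' @return The coupling matrix `P` with attributes `potentials` (duals
#'   `f`, `g`), `iterations` and `residual`.
#' @export
sinkhorn <- function(C, a = NULL, b = NULL, eps, max_iter = 1000L,
                     tol = 1e-9, potentials = NULL, anneal = TRUE,
                     on_fail = c("error", "round")) {
  on_fail <- match.arg(on_fail)
  if (eps <= 0) stop_bad("eps must be > 0, got %g", eps)
  n <- nrow(C); np <- ncol(C)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / np, np)
  if (any(a <= 0) || any(b <= 0) ||
      abs(sum(a) - 1) > 1e-8 || abs(sum(b) - 1) > 1e-8)
    stop_bad("marginals must be positive and sum to 1")
  f <- if (!is.null(potentials)) potentials$f else numeric(n)
  g <- if (!is.null(potentials)) potentials$g else numeric(np)
  # epsilon scaling: approach the target regularization through a
  # geometric schedule, carrying the dual potentials, which restores
  # fast convergence when eps is far below the cost scale
  if (anneal && is.null(potentials)) {
    eps0 <- max(C) / 10
    while (eps0 > eps * 1.0001) {
      st <- sinkhorn_core(C, a, b, eps0, 100L, tol * 100, f, g)
      f <- st$f; g <- st$g
      eps0 <- eps0 / 3
    }
  }
  st <- sinkhorn_core(C, a, b, eps, max_iter, tol, f, g)
  if (st$residual > tol) {
    if (on_fail == "error")
      stop_bad("Sinkhorn did not converge in %d iterations (residual %.3g > tol %.3g)",
               max_iter, st$residual, tol)
    st$P <- round_coupling(st$P, a, b)
  }
  structure(st$P,
            potentials = list(f = st$f, g = st$g),
            iterations = st$iterations, residual = st$residual)
}

# Stabilized scaling iterations at a fixed eps, starting from dual
# potentials (f, g); returns the plan, updated duals and the residual.
sinkhorn_core <- function(C, a, b, eps, max_iter, tol, f, g) {
  n <- nrow(C); np <- ncol(C)
  lse_rows <- function(M) {
    mx <- apply(M, 1L, max)
    mx + log(rowSums(exp(M - mx)))
  }
  Kt <- exp((outer(f, g, "+") - C) / eps)
  u <- rep(1, n); v <- rep(1, np)
  absorb_at <- 1e30
  iter <- 0L
  residual <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    Kv <- as.vector(Kt %*% v)
    if (any(Kv <= 0) || any(!is.finite(Kv))) {
      # log-domain sweep: f_i = eps log a_i - eps lse_j((g_j - C_ij)/eps)
      g <- g + eps * log(pmax(v, .Machine$double.xmin))
      f <- eps * log(a) -
        eps * lse_rows((matrix(g, n, np, byrow = TRUE) - C) / eps)
      g <- eps * log(b) -
        eps * lse_rows(t((matrix(f, n, np) - C) / eps))
      Kt <- exp((outer(f, g, "+") - C) / eps)
      u <- rep(1, n); v <- rep(1, np)
      next
    }
    u <- a / Kv
    Ku <- as.vector(crossprod(Kt, u))
    v <- b / Ku
    if (max(u, v) > absorb_at || min(u, v) < 1 / absorb_at) {
      f <- f + eps * log(u); g <- g + eps * log(v)
      Kt <- exp((outer(f, g, "+") - C) / eps)
      u <- rep(1, n); v <- rep(1, np)
    }
    if (iter %% 5L == 0L || iter == max_iter) {
      P <- u * Kt * rep(v, each = n)
      residual <- max(abs(rowSums(P) - a))
      if (residual < tol) break
    }
  }
  P <- u * Kt * rep(v, each = n)
  residual <- max(max(abs(rowSums(P) - a)), max(abs(colSums(P) - b)))
  list(P = P, f = f + eps * log(u), g = g + eps * log(v),
       iterations = iter, residual = residual)
}

# Project an almost-feasible plan onto Pi(a, b): cap row and column
# scalings at 1, then add the rank-one correction that restores the
# marginals exactly.
round_coupling <- function(P, a, b) {
  x <- pmin(a / pmax(rowSums(P), .Machine$double.xmin), 1)
  P <- P * x
  y <- pmin(b / pmax(colSums(P), .Machine$double.xmin), 1)
  P <- P * rep(y, each = nrow(P))
  r <- a - rowSums(P)
  cc <- b - colSums(P)
  s <- sum(abs(r))
  if (s > 0) P <- P + outer(r, cc) / s
  P
}

#' Orthogonal Procrustes under a coupling
#'
#' Solves `min_{O in O_d} <P, d^2(Z O, Z')>_F` for fixed `P`: the singular
#' value decomposition `Z' P Z' = U S V'` gives `O = U V'`. Reflections
#' are permitted (the full orthogonal group, not only rotations).
#'
#' @param Z n x d embedding.
#' @param P n x n' coupling.
#' @param Zp n' x d embedding.
#' @return d x d orthogonal matrix.
#' @export
orthogonal_procrustes <- function(Z, P, Zp) {
  M <- crossprod(Z, P %*% Zp)
  if (max(abs(M)) == 0)
    stop_bad("degenerate all-zero cross matrix Z' P Z'")
  s <- svd(M)
  tcrossprod(s$u, s$v)
}

#' Wasserstein-Procrustes alternation
#'
#' Alternates entropic optimal transport (update of the plan `P` with the
#' orthogonal map `O` fixed) and orthogonal Procrustes (update of `O` with
#' `P` fixed), starting from `O_init`. Each half-step solves its
#' subproblem exactly, so the objective `<P, C(O)>_F - eps H(P)` is
#' non-increasing across alternations.
#'
#' @param Z,Zp Embeddings of the two domains.
#' @param a,b Marginals (defaults: uniform).
#' @param eps Entropic regularization.
#' @param n_alternations Number of full (Sinkhorn + Procrustes)
#'   alternations; `0` returns `O_init` and its Sinkhorn plan.
#' @param O_init Initial orthogonal matrix (default identity).
#' @param max_iter,tol Passed to [sinkhorn()].
#' @param potentials Optional warm-start dual potentials.
#' @param on_fail Non-convergence policy forwarded to [sinkhorn()].
#' @return List with `P`, `O`, `objective` (value after each `P` update)
#'   and `potentials`.
#' @export
wasserstein_procrustes <- function(Z, Zp, a = NULL, b = NULL, eps,
                                   n_alternations = 1L,
                                   O_init = NULL,
                                   max_iter = 1000L, tol = 1e-9,
                                   potentials = NULL,
                                   on_fail = c("error", "round")) {
  on_fail <- match.arg(on_fail)
  d <- ncol(Z)
  O <- if (is.null(O_init)) diag(d) else O_init
  obj <- numeric(0)
  P <- sinkhorn(squared_distance_cost(Z, O, Zp), a, b, eps = eps,
                max_iter = max_iter, tol = tol, potentials = potentials,
                on_fail = on_fail)
  obj <- c(obj, sum(P * squared_distance_cost(Z, O, Zp)) -
             eps * coupling_entropy(P))
  if (n_alternations > 0) {
    for (it in seq_len(n_alternations)) {
      O <- orthogonal_procrustes(Z, P, Zp)
      P <- sinkhorn(squared_distance_cost(Z, O, Zp), a, b, eps = eps,
                    max_iter = max_iter, tol = tol,
                    potentials = attr(P, "potentials"), on_fail = on_fail)
      obj <- c(obj, sum(P * squared_distance_cost(Z, O, Zp)) -
                 eps * coupling_entropy(P))
    }
  }
  list(P = P, O = O, objective = obj,
       potentials = attr(P, "potentials"))
}
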
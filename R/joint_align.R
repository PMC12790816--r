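# The outer Joint MDS alternation for two domains, its three-domain
# extension via successive pairwise rounds against a core domain, and a
# hyperparameter grid search.

#' Joint MDS: align and embed two domains
#'
#' Given two within-domain dissimilarity matrices, minimizes
#' `stress(Z, D, W) + stress(Z', D', W') + 2 lambda <P, d^2(Z O, Z')>_F`
#' over embeddings `Z, Z'`, a transport plan `P` with fixed marginals and
#' an orthogonal map `O`. Embeddings are initialized by SMACOF from random
#' normal configurations; the algorithm then alternates (i) a
#' Wasserstein-Procrustes update of `(P, O)` with the embeddings fixed and
#' (ii) SMACOF majorization steps on the coupled configuration with
#' `(P, O)` fixed, until the relative Frobenius change of `P` falls below
#' `tol_P` or `max_outer` outer iterations are reached.
#'
#' Because the two independently initialized embeddings differ by an
#' arbitrary rigid motion, the first `(P, O)` update is solved from
#' `n_restarts` random orthogonal starts (plus the identity) and the start
#' with the lowest entropic matching objective is kept; later iterations
#' warm-start from the current `O` and dual potentials. All randomness
#' derives from `seed`, so a fixed seed gives a bitwise-identical result.
#'
#' @param D1,D2 Square dissimilarity matrices (n x n and n' x n').
#' @param d Embedding dimension.
#' @param lambda Matching penalty `>= 0`; `0` decouples the two domains.
#' @param eps Entropic regularization `> 0`.
#' @param max_outer Maximum outer alternations.
#' @param tol_P Relative Frobenius change of `P` declaring convergence.
#' @param seed Integer seed for all randomness.
#' @param a,b Transport marginals (defaults: uniform).
#' @param W1,W2 MDS weight matrices (defaults: uniform `1/n^2`).
#' @param init_method Initialization of the per-domain embeddings:
#'   `"torgerson"` (classical MDS, deterministic; the default) or
#'   `"random"` (seeded standard normal coordinates, as in
#'   [init_embedding()]). Classical MDS starts both domains near the
#'   same stress basin in a canonical principal-axes orientation, which
#'   makes the downstream registration markedly more reliable on
#'   tree-like manifolds where random starts can land in structurally
#'   different local minima that no rigid map relates.
#' @param init_Z1,init_Z2 Optional initial embeddings, bypassing the
#'   initialization (used by [joint_mds3()] step 4).
#' @param n_restarts Size of the orthogonal-start fan for the first
#'   matching step (for `d = 2`: `n_restarts` rotations plus their
#'   reflections).
#' @param max_inner Maximum SMACOF steps per outer iteration.
#' @param mds_iter Iteration cap for the per-domain SMACOF
#'   initialization.
#' @param eps_scan Softened entropic regularization used only while
#'   scanning orientation starts (the final match uses `eps`).
#' @param scan_size Maximum number of points (evenly strided) used in
#'   the orientation scan.
#' @param refine_top Number of leading scan candidates sharpened on the
#'   full problem before committing to an orientation.
#' @param sinkhorn_iter,sinkhorn_tol Iteration cap and marginal-residual
#'   tolerance for the inner Sinkhorn solves (warm-started across outer
#'   iterations).
#' @return An object of class `joint_mds`: list with `Z1`, `Z2` (both in
#'   the common frame, i.e. `Z1` is returned as `Z O`), `P`, `O`,
#'   `objective` (trace of the joint objective including the entropic
#'   matching penalty `-2 lambda eps H(P)` — the quantity every
#'   half-step of the alternation decreases), `converged`,
#'   `iterations`.
#' @export
joint_mds <- function(D1, D2, d = 2L, lambda = 1, eps = 0.01,
                      max_outer = 100L, tol_P = 1e-5, seed = 1L,
                      a = NULL, b = NULL, W1 = NULL, W2 = NULL,
                      init_method = c("torgerson", "random"),
                      init_Z1 = NULL, init_Z2 = NULL,
                      n_restarts = 12L, max_inner = 10L,
                      mds_iter = 300L, eps_scan = 0.05, scan_size = 120L,
                      refine_top = 3L,
                      sinkhorn_iter = 20000L, sinkhorn_tol = 1e-6) {
  check_square_dissimilarity(D1, "D1")
  check_square_dissimilarity(D2, "D2")
  if (lambda < 0) stop_bad("lambda must be >= 0")
  if (eps <= 0) stop_bad("eps must be > 0")
  n <- nrow(D1); np <- nrow(D2)
  if (is.null(W1)) W1 <- uniform_weights(n)
  if (is.null(W2)) W2 <- uniform_weights(np)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / np, np)

  init_method <- match.arg(init_method)
  Z <- if (!is.null(init_Z1)) as.matrix(init_Z1) else
    start_embedding(D1, d, init_method, derive_seed(seed, 1L))
  Zp <- if (!is.null(init_Z2)) as.matrix(init_Z2) else
    start_embedding(D2, d, init_method, derive_seed(seed, 2L))
  Z <- weighted_mds(D1, W1, d, init = Z, max_iter = mds_iter)$embedding
  Zp <- weighted_mds(D2, W2, d, init = Zp, max_iter = mds_iter)$embedding

  O <- diag(d)
  P <- NULL
  pot <- NULL
  obj_trace <- numeric(0)
  converged <- FALSE
  iter_used <- 0L

  for (outer in seq_len(max_outer)) {
    if (outer == 1L) {
      # multi-start matching: the relative orientation of the two fresh
      # embeddings is arbitrary, so scan a fan of orthogonal starts at a
      # softened regularization (wider basins) on an evenly strided
      # subsample of points, then sharpen the best start on the full
      # problem
      starts <- orthogonal_starts(d, n_restarts, derive_seed(seed, 3L))
      eps_soft <- max(eps, eps_scan)
      si <- unique(round(seq(1L, n, length.out = min(n, scan_size))))
      sj <- unique(round(seq(1L, np, length.out = min(np, scan_size))))
      Zs <- Z[si, , drop = FALSE]; Zps <- Zp[sj, , drop = FALSE]
      as <- rep(1 / length(si), length(si))
      bs <- rep(1 / length(sj), length(sj))
      scan_obj <- numeric(length(starts))
      scan_O <- vector("list", length(starts))
      for (ii in seq_along(starts)) {
        wp <- wasserstein_procrustes(Zs, Zps, as, bs, eps = eps_soft,
                                     n_alternations = 6L,
                                     O_init = starts[[ii]],
                                     max_iter = sinkhorn_iter,
                                     tol = sinkhorn_tol, on_fail = "round")
        scan_obj[ii] <- min(wp$objective)
        scan_O[[ii]] <- wp$O
      }
      # near-symmetric configurations leave the scan objectives of the
      # true and a flipped orientation almost tied: sharpen the leading
      # candidates on the full problem and let the exact objective decide
      top <- order(scan_obj)[seq_len(min(refine_top, length(starts)))]
      wp <- NULL
      for (ii in top) {
        cand <- wasserstein_procrustes(Z, Zp, a, b, eps = eps,
                                       n_alternations = 4L,
                                       O_init = scan_O[[ii]],
                                       max_iter = sinkhorn_iter,
                                       tol = sinkhorn_tol, on_fail = "round")
        if (is.null(wp) || min(cand$objective) < min(wp$objective))
          wp <- cand
      }
    } else {
      wp <- wasserstein_procrustes(Z, Zp, a, b, eps = eps,
                                   n_alternations = 1L, O_init = O,
                                   potentials = pot,
                                   max_iter = sinkhorn_iter,
                                   tol = sinkhorn_tol, on_fail = "round")
    }
    P_new <- wp$P; O <- wp$O; pot <- wp$potentials

    rel <- if (is.null(P)) Inf else
      norm(P_new - P, "F") / max(norm(P, "F"), .Machine$double.eps)
    P <- P_new

    # SMACOF steps on the stacked coupled configuration with (P, O)
    # fixed; the stacked stress equals the joint objective
    entH <- 2 * lambda * eps * coupling_entropy(P)
    if (max_inner > 0L && lambda == 0) {
      # decoupled objective: the plan cannot influence the embeddings
      u1 <- is_uniform_weights(W1); u2 <- is_uniform_weights(W2)
      e1 <- smacof_engine(Z, D1, W1, WD = W1 * D1,
                          Vinv = if (u1) NULL else guttman_vinv(W1),
                          unif_w = if (u1) W1[1L, 2L] else NULL,
                          max_steps = max_inner, tol = 1e-6)
      e2 <- smacof_engine(Zp, D2, W2, WD = W2 * D2,
                          Vinv = if (u2) NULL else guttman_vinv(W2),
                          unif_w = if (u2) W2[1L, 2L] else NULL,
                          max_steps = max_inner, tol = 1e-6)
      Z <- e1$X; Zp <- e2$X
      obj_trace <- c(obj_trace, e1$trace + utils::tail(e2$trace, 1L))
    } else if (max_inner > 0L) {
      Dblk <- rbind(cbind(D1, matrix(0, n, np)),
                    cbind(matrix(0, np, n), D2))
      Wblk <- rbind(cbind(W1, lambda * P), cbind(lambda * t(P), W2))
      Vinv <- guttman_vinv(Wblk)
      eng <- smacof_engine(rbind(Z %*% O, Zp), Dblk, Wblk,
                           WD = Wblk * Dblk, Vinv = Vinv,
                           max_steps = max_inner, tol = 1e-6)
      Z <- eng$X[seq_len(n), , drop = FALSE] %*% t(O)
      Zp <- eng$X[n + seq_len(np), , drop = FALSE]
      obj_trace <- c(obj_trace, eng$trace - entH)
    } else {
      obj_trace <- c(obj_trace,
                     joint_objective(Z, Zp, D1, D2, W1, W2, P, O, lambda) -
                       entH)
    }
    iter_used <- outer
    if (rel < tol_P) { converged <- TRUE; break }
  }

  structure(list(Z1 = Z %*% O, Z2 = Zp, P = unclass_coupling(P), O = O,
                 objective = obj_trace, converged = converged,
                 iterations = iter_used,
                 d = d, lambda = lambda, eps = eps, seed = seed),
            class = "joint_mds")
}

# Initial configuration for one domain: classical (Torgerson) MDS in a
# canonical principal-axes frame, or seeded random normal coordinates.
# Degenerate classical solutions with fewer than d positive eigenvalues
# are padded with small seeded noise so SMACOF can leave the subspace.
start_embedding <- function(D, d, method, seed) {
  if (method == "random") return(init_embedding(nrow(D), d, seed))
  cm <- suppressWarnings(stats::cmdscale(D, k = d))
  if (ncol(cm) < d) {
    pad <- 1e-6 * init_embedding(nrow(D), d - ncol(cm), seed)
    cm <- cbind(cm, pad)
  }
  unname(cm)
}

# strip sinkhorn attributes so results compare cleanly
unclass_coupling <- function(P) {
  attributes(P) <- list(dim = dim(P))
  P
}

# Deterministic set of orthogonal d x d starting points for the matching
# scan. For d = 2 the orthogonal group is one-dimensional, so a uniform
# fan of m rotations plus their reflections covers it with gaps of
# 360/m degrees; for d > 2, QR factors of seeded Gaussian matrices.
orthogonal_starts <- function(d, m, seed) {
  if (m <= 0) return(list(diag(d)))
  if (d == 2L) {
    ang <- 2 * pi * (seq_len(m) - 1L) / m
    rots <- lapply(ang, function(a)
      matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L))
    refl <- lapply(rots, function(Rm) Rm %*% diag(c(1, -1)))
    c(rots, refl)
  } else {
    c(list(diag(d)),
      local_seed(seed, lapply(seq_len(2L * m), function(i) {
        qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
      })))
  }
}

#' Print method for joint_mds results
#' @param x A `joint_mds` object.
#' @param ... Ignored.
#' @export
print.joint_mds <- function(x, ...) {
  cat(sprintf(
    "Joint MDS alignment: n = %d / %d, d = %d, lambda = %g, eps = %g\n",
    nrow(x$Z1), nrow(x$Z2), x$d, x$lambda, x$eps))
  cat(sprintf("  outer iterations: %d (converged: %s)\n",
              x$iterations, x$converged))
  cat(sprintf("  final objective: %.6g\n", utils::tail(x$objective, 1L)))
  invisible(x)
}

#' Apply the orthogonal alignment map to an embedding
#'
#' In the matching objective the orthogonal map acts on the first
#' domain's frame: `side = "first"` returns `Z O`, `side = "second"`
#' returns `Z` unchanged (the reference frame).
#'
#' @param Z n x d embedding.
#' @param O d x d orthogonal matrix.
#' @param side `"first"` or `"second"`.
#' @return Transformed embedding.
#' @export
apply_alignment <- function(Z, O, side = c("first", "second")) {
  side <- match.arg(side)
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(O)) stop_bad("dimension mismatch between Z and O")
  if (side == "first") Z %*% O else Z
}

#' Joint MDS3: align three domains through a core domain
#'
#' Three successive pairwise Joint MDS rounds. With domain `core` playing
#' A and the other two playing B and C: (3a) align B to A and (3b) align
#' C to A, giving `A_B, B_A` and `A_C, C_A`; (4) run Joint MDS on the
#' Euclidean dissimilarities of the two core embeddings `A_B` and `A_C`
#' (initialized from those embeddings) to obtain the merged core
#' embedding `A_BC` together with a plan `P` and orthogonal map `O`
#' between the two branch frames; (5) carry `B_A` into the common frame
#' with that `O` (`B_AC = B_A O`) while `C_A` already lives in the common
#' (A_C-side) frame (`C_AB = C_A`). Steps 4-5 apply isometries only, so
#' within-domain geometry is untouched.
#'
#' @param D1,D2,D3 Square n x n dissimilarity matrices (equal n).
#' @param core Which domain (1, 2 or 3) is the core dataset A.
#' @param d,lambda,eps,max_outer,tol_P,seed,n_restarts,max_inner,mds_iter,init_method
#'   As in [joint_mds()]; applied to every round.
#' @return An object of class `joint_mds3`: list with `Z1`, `Z2`, `Z3`
#'   (embeddings of domains 1..3 in one common d-space), `core`, and the
#'   intermediate pairwise results `fit_core_b`, `fit_core_c`,
#'   `fit_merge`.
#' @export
joint_mds3 <- function(D1, D2, D3, core = 1L, d = 2L, lambda = 1,
                       eps = 0.01, max_outer = 100L, tol_P = 1e-5,
                       seed = 1L, n_restarts = 12L, max_inner = 10L,
                       mds_iter = 300L,
                       init_method = c("torgerson", "random")) {
  init_method <- match.arg(init_method)
  Ds <- list(D1, D2, D3)
  for (i in 1:3) check_square_dissimilarity(Ds[[i]], paste0("D", i))
  n <- nrow(D1)
  if (nrow(D2) != n || nrow(D3) != n)
    stop_bad("joint_mds3 requires equal sample counts (got %d, %d, %d)",
             n, nrow(D2), nrow(D3))
  core <- as.integer(core)
  if (!core %in% 1:3) stop_bad("core must be 1, 2 or 3")
  others <- setdiff(1:3, core)

  fit_b <- joint_mds(Ds[[core]], Ds[[others[1L]]], d = d, lambda = lambda,
                     eps = eps, max_outer = max_outer, tol_P = tol_P,
                     seed = derive_seed(seed, 11L), n_restarts = n_restarts,
                     max_inner = max_inner, mds_iter = mds_iter,
                     init_method = init_method)
  fit_c <- joint_mds(Ds[[core]], Ds[[others[2L]]], d = d, lambda = lambda,
                     eps = eps, max_outer = max_outer, tol_P = tol_P,
                     seed = derive_seed(seed, 12L), n_restarts = n_restarts,
                     max_inner = max_inner, mds_iter = mds_iter,
                     init_method = init_method)
  A_B <- fit_b$Z1; B_A <- fit_b$Z2
  A_C <- fit_c$Z1; C_A <- fit_c$Z2

  # step 4: merge the two core branches in a final matching-only round
  # (embeddings fixed, max_inner = 0): the Wasserstein-Procrustes
  # alternation converges on a plan P and a map O from the A_B-side
  # frame onto the A_C-side frame; keeping the configurations fixed
  # preserves the step-3 alignments of B_A and C_A exactly
  DA_B <- as.matrix(stats::dist(A_B))
  DA_C <- as.matrix(stats::dist(A_C))
  fit_m <- joint_mds(DA_B, DA_C, d = d, lambda = lambda, eps = eps,
                     max_outer = max_outer, tol_P = tol_P,
                     seed = derive_seed(seed, 13L),
                     init_Z1 = A_B, init_Z2 = A_C,
                     n_restarts = n_restarts, max_inner = 0L,
                     mds_iter = 0L)

  A_BC <- fit_m$Z2               # common frame = A_C-side frame
  B_AC <- apply_alignment(B_A, fit_m$O, "first")
  C_AB <- apply_alignment(C_A, fit_m$O, "second")

  Z <- vector("list", 3L)
  Z[[core]] <- A_BC
  Z[[others[1L]]] <- B_AC
  Z[[others[2L]]] <- C_AB
  structure(list(Z1 = Z[[1L]], Z2 = Z[[2L]], Z3 = Z[[3L]], core = core,
                 fit_core_b = fit_b, fit_core_c = fit_c, fit_merge = fit_m,
                 d = d, lambda = lambda, eps = eps, seed = seed),
            class = "joint_mds3")
}

#' Print method for joint_mds3 results
#' @param x A `joint_mds3` object.
#' @param ... Ignored.
#' @export
print.joint_mds3 <- function(x, ...) {
  cat(sprintf(
    "Joint MDS3 alignment: n = %d, d = %d, core domain = %d\n",
    nrow(x$Z1), x$d, x$core))
  cat(sprintf("  lambda = %g, eps = %g\n", x$lambda, x$eps))
  invisible(x)
}

#' Hyperparameter grid search for pairwise Joint MDS
#'
#' Evaluates [joint_mds()] for every combination of `k` (geodesic
#' neighbours), `eps` and `lambda`, averaging the criterion over
#' `n_seeds` seeds, and returns the best cell plus the full score table.
#' Inputs are the two *Euclidean* dissimilarity matrices; geodesic
#' distances are recomputed per `k` (and max-normalized).
#'
#' @param E1,E2 Euclidean dissimilarity matrices of the two domains.
#' @param k_grid,eps_grid,lambda_grid Non-empty numeric grids.
#' @param d Embedding dimension.
#' @param criterion `"foscttm"` (minimized; requires row correspondence
#'   between the two domains) or `"objective"` (final joint objective,
#'   minimized) or `"transfer"` (label transfer accuracy, maximized;
#'   requires `labels`).
#' @param labels Named/plain label vector for `criterion = "transfer"`.
#' @param n_seeds Seeds per cell (base_seed .. base_seed + n_seeds - 1).
#' @param base_seed First seed.
#' @param ... Further arguments passed to [joint_mds()].
#' @return List with `best` (list `k`, `eps`, `lambda`) and `table`
#'   (data.frame of all cells with mean scores). Ties resolve to the
#'   lexicographically smallest `(k, eps, lambda)`.
#' @export
grid_search <- function(E1, E2, k_grid, eps_grid, lambda_grid, d = 2L,
                        criterion = c("foscttm", "objective", "transfer"),
                        labels = NULL, n_seeds = 1L, base_seed = 0L, ...) {
  criterion <- match.arg(criterion)
  if (!length(k_grid) || !length(eps_grid) || !length(lambda_grid))
    stop_bad("all hyperparameter grids must be non-empty")
  if (criterion == "transfer" && is.null(labels))
    stop_bad("criterion 'transfer' requires labels")
  cells <- expand.grid(k = sort(k_grid), eps = sort(eps_grid),
                       lambda = sort(lambda_grid),
                       KEEP.OUT.ATTRS = FALSE)
  # lexicographic order in (k, eps, lambda) so which.min/max tie-breaks
  cells <- cells[order(cells$k, cells$eps, cells$lambda), , drop = FALSE]
  geo <- new.env(parent = emptyenv())
  get_geo <- function(E, tag, k) {
    key <- paste0(tag, "_", k)
    if (is.null(geo[[key]]))
      geo[[key]] <- normalize_dissimilarity(geodesic_distances(E, k))
    geo[[key]]
  }
  scores <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    k <- cells$k[i]
    D1 <- get_geo(E1, "a", k); D2 <- get_geo(E2, "b", k)
    vals <- vapply(seq_len(n_seeds), function(s) {
      fit <- joint_mds(D1, D2, d = d, lambda = cells$lambda[i],
                       eps = cells$eps[i],
                       seed = derive_seed(base_seed, s - 1L), ...)
      switch(criterion,
             foscttm = foscttm(fit$Z1, fit$Z2),
             objective = utils::tail(fit$objective, 1L),
             transfer = label_transfer_accuracy(fit$Z1, labels, fit$Z2,
                                                labels))
    }, numeric(1))
    scores[i] <- mean(vals)
  }
  cells$score <- scores
  best_i <- if (criterion == "transfer") which.max(scores) else which.min(scores)
  list(best = list(k = cells$k[best_i], eps = cells$eps[best_i],
                   lambda = cells$lambda[best_i]),
       table = cells)
}
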
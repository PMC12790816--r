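test_that("squared-distance costs match the definition", {
  Z <- matrix(c(0, 2), 2, 1)
  expect_equal(squared_distance_cost(Z, diag(1), Z),
               matrix(c(0, 4, 4, 0), 2))

  Z2 <- rand_points(3, 2, 20, ids = FALSE)
  O <- rotation2(0.3)
  Zp <- rand_points(4, 2, 21, ids = FALSE)
  C <- squared_distance_cost(Z2, O, Zp)
  for (i in 1:3) for (j in 1:4)
    expect_equal(C[i, j], sum((Z2[i, ] %*% O - Zp[j, ])^2))

  expect_equal(diag(squared_distance_cost(Z2, O, Z2 %*% O)), rep(0, 3))
  expect_error(squared_distance_cost(Z2, diag(3), Zp), "dimension mismatch")
})

test_that("coupling entropy uses the Sinkhorn-exact convention", {
  n <- 3; np <- 4
  U <- matrix(1 / (n * np), n, np)
  expect_equal(coupling_entropy(U), log(n * np) + 1)
  perm <- diag(2) / 2
  expect_equal(coupling_entropy(perm), log(2) + 1)
  # maximum-entropy property
  P <- jointmds:::local_seed(1, {M <- matrix(rexp(12), 3); M / sum(M)})
  expect_lte(coupling_entropy(P), coupling_entropy(U))
})

test_that("sinkhorn solves degenerate and sharp cases exactly", {
  # constant cost: the plan is the independent coupling
  a <- c(0.2, 0.3, 0.5); b <- c(0.6, 0.4)
  P <- sinkhorn(matrix(1, 3, 2), a, b, eps = 0.5)
  expect_equal(unclass(P), outer(a, b), tolerance = 1e-7,
               ignore_attr = TRUE)

  # sharp regularization recovers the exact assignment
  C <- matrix(c(0, 1, 1, 0), 2)
  P <- sinkhorn(C, eps = 0.01)
  expect_equal(unclass(P), diag(2) / 2, tolerance = 1e-4,
               ignore_attr = TRUE)

  expect_error(sinkhorn(C, eps = -1), "eps must be")
  expect_error(sinkhorn(C, a = c(2, 1), b = c(0.5, 0.5), eps = 1),
               "marginals")
})

test_that("sinkhorn marginals are conserved across random instances", {
  for (seed in 1:25) {
    C <- jointmds:::local_seed(seed, matrix(runif(20), 4, 5))
    a <- rep(1 / 4, 4); b <- rep(1 / 5, 5)
    P <- sinkhorn(C, a, b, eps = 0.05, max_iter = 5000)
    expect_lt(max(abs(rowSums(P) - a)), 1e-6)
    expect_lt(max(abs(colSums(P) - b)), 1e-6)
    expect_true(all(P >= 0))
    expect_equal(sum(P), 1, tolerance = 1e-8)
  }
})

test_that("small-eps plans approach the exact optimal assignment", {
  for (n in 2:4) for (seed in 1:5) {
    C <- jointmds:::local_seed(100 * n + seed, matrix(runif(n * n), n))
    lp <- lp_assignment_cost(C)
    P <- sinkhorn(C, eps = 0.002, max_iter = 50000, tol = 1e-7)
    expect_equal(sum(P * C), lp$cost, tolerance = 1e-3)
    # mass concentrates on the optimal permutation
    expect_gt(sum(P[cbind(seq_len(n), lp$perm)]), 0.95)
  }
})

test_that("the entropic objective matches an independent dual solver", {
  # generic convex solver on the smooth unconstrained dual
  C <- jointmds:::local_seed(7, matrix(runif(9), 3))
  a <- rep(1 / 3, 3); b <- rep(1 / 3, 3)
  eps <- 0.1
  dual <- function(th) {
    f <- th[1:3]; g <- th[4:6]
    eps * sum(exp((outer(f, g, "+") - C) / eps)) - sum(f * a) - sum(g * b)
  }
  opt <- optim(rep(0, 6), dual, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  P_opt <- exp((outer(opt$par[1:3], opt$par[4:6], "+") - C) / eps)
  obj_oracle <- sum(P_opt * C) - eps * coupling_entropy(P_opt)
  P <- sinkhorn(C, a, b, eps = eps, max_iter = 10000)
  obj <- sum(P * C) - eps * coupling_entropy(P)
  expect_lt(abs(obj - obj_oracle), 1e-6)
})

test_that("orthogonal Procrustes recovers planted transforms", {
  Z <- rand_points(10, 2, 30, ids = FALSE)
  O <- orthogonal_procrustes(Z, diag(10) / 10, Z)
  expect_equal(O, diag(2), tolerance = 1e-10)

  R <- rotation2(pi / 6)
  O <- orthogonal_procrustes(Z, diag(10) / 10, Z %*% R)
  expect_lt(max(abs(O - R)), 1e-8)
  expect_lt(max(abs(crossprod(O) - diag(2))), 1e-8)

  expect_error(orthogonal_procrustes(Z, matrix(0, 10, 10), Z),
               "degenerate")
})

test_that("wasserstein-procrustes alternation is monotone and recovers rotations", {
  Z <- rand_points(12, 2, 31, ids = FALSE)
  R <- rotation2(0.25)
  Zr <- Z %*% R
  wp <- wasserstein_procrustes(Z, Zr, eps = 0.005, n_alternations = 8,
                               max_iter = 20000, tol = 1e-6)
  expect_true(all(diff(wp$objective) <= 1e-9))
  expect_gt(sum(diag(wp$P)), 0.9)
  expect_equal(wp$O, R, tolerance = 1e-3)

  # zero alternations: the initial transform and its plan
  wp0 <- wasserstein_procrustes(Z, Zr, eps = 0.05, n_alternations = 0,
                                max_iter = 50000, tol = 1e-6)
  expect_identical(wp0$O, diag(2))
  expect_length(wp0$objective, 1L)

  # identical embeddings couple diagonally at small eps
  wps <- wasserstein_procrustes(Z, Z, eps = 0.005, n_alternations = 5,
                                max_iter = 50000, tol = 1e-6)
  expect_gt(sum(diag(wps$P)), 0.9)
})
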
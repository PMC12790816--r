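test_that("random initialization is a pure function of its seed", {
  A <- init_embedding(3, 2, seed = 0)
  B <- init_embedding(3, 2, seed = 0)
  expect_identical(A, B)
  expect_false(isTRUE(all.equal(A, init_embedding(3, 2, seed = 1))))
  expect_error(init_embedding(3, 0, seed = 0), ">= 1")
})

test_that("stress follows the ordered-pair convention", {
  # two points at distance 1 embedding a target distance of 2, unit
  # weights on both ordered pairs -> stress (2 - 1)^2 * 2
  Z <- matrix(c(0, 1, 0, 0), 2, 2)
  D <- matrix(c(0, 2, 2, 0), 2)
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(mds_stress(Z, D, W), 2)
  expect_equal(mds_stress(Z, D, 2 * W), 4)   # linear in W

  # an exactly realized configuration has zero stress
  X <- rand_points(6, 2, 10, ids = FALSE)
  expect_equal(mds_stress(X, unname(pairwise_euclidean(X))), 0)
  expect_error(mds_stress(Z, matrix(0, 3, 3)), "shape mismatch")
})

test_that("the Guttman transform never increases stress", {
  for (seed in 1:20) {
    D <- rand_diss(5, 3, seed)
    Z <- init_embedding(5, 2, seed + 100)
    s0 <- mds_stress(Z, D)
    s1 <- mds_stress(smacof_step(Z, D), D)
    expect_lte(s1, s0 + 1e-12)
  }
})

test_that("a centred zero-stress configuration is a fixed point", {
  X <- rand_points(5, 2, 12, ids = FALSE)
  X <- scale(X, center = TRUE, scale = FALSE)   # Guttman updates re-centre
  attr(X, "scaled:center") <- NULL
  D <- unname(pairwise_euclidean(X))
  expect_equal(smacof_step(X, D), unclass(X), tolerance = 1e-12)
})

test_that("coincident points do not produce division by zero", {
  Z <- matrix(c(1, 1, 0, 1, 1, 0), 3, 2, byrow = TRUE)  # rows 1,2 coincide
  D <- rand_diss(3, 2, 13)
  out <- smacof_step(Z, D)
  expect_true(all(is.finite(out)))
})

test_that("weighted MDS drives stress to zero on embeddable fixtures", {
  X <- rand_points(4, 2, 14, ids = FALSE)
  D <- unname(pairwise_euclidean(X))
  fit <- weighted_mds(D, d = 2, init = init_embedding(4, 2, 1),
                      max_iter = 500, tol = 1e-12)
  expect_lt(tail(fit$trace, 1), 1e-6)
  expect_true(all(diff(fit$trace) <= 1e-12))

  # three collinear points, distances 1, 1, 2, recoverable in d = 1
  D3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  fit1 <- weighted_mds(D3, d = 1, init = init_embedding(3, 1, 2),
                       max_iter = 2000, tol = 1e-14)
  got <- sort(as.vector(dist(fit1$embedding)))
  expect_equal(got, c(1, 1, 2), tolerance = 1e-4)
})

test_that("SMACOF agrees with classical scaling on Euclidean data", {
  # for exactly Euclidean dissimilarities both solvers recover the true
  # pairwise distances
  X <- rand_points(10, 3, 22, ids = FALSE)
  D <- unname(pairwise_euclidean(X))
  sm <- weighted_mds(D, d = 3, init = init_embedding(10, 3, 4),
                     max_iter = 2000, tol = 1e-14)
  cl <- cmdscale(D, k = 3)
  expect_equal(c(dist(sm$embedding)), c(dist(cl)), tolerance = 1e-5)
  expect_equal(c(dist(sm$embedding)), c(D[lower.tri(D)]), tolerance = 1e-5)
})

test_that("weighted MDS with max_iter = 0 returns the initial embedding", {
  D <- rand_diss(5, 2, 15)
  init <- init_embedding(5, 2, 3)
  fit <- weighted_mds(D, d = 2, init = init, max_iter = 0)
  expect_identical(fit$embedding, init)
  expect_equal(fit$iterations, 0L)
})

test_that("stress traces are monotone for non-uniform weights too", {
  for (seed in 1:5) {
    D <- rand_diss(6, 3, seed + 30)
    W <- jointmds:::local_seed(seed, {
      M <- matrix(runif(36), 6)
      M <- (M + t(M)) / 2
      diag(M) <- 0
      M
    })
    fit <- weighted_mds(D, W = W, d = 2, init = init_embedding(6, 2, seed),
                        max_iter = 50)
    expect_true(all(diff(fit$trace) <= 1e-12))
  }
})

test_that("the coupled step decouples when lambda is zero", {
  D1 <- rand_diss(6, 2, 40); D2 <- rand_diss(6, 2, 41)
  Z1 <- init_embedding(6, 2, 1); Z2 <- init_embedding(6, 2, 2)
  W <- uniform_weights(6)
  P <- matrix(1 / 36, 6, 6)
  st <- joint_stress_step(Z1, Z2, D1, D2, W, W, P, diag(2), lambda = 0)
  expect_equal(st$Z, smacof_step(Z1, D1, W))
  expect_equal(st$Zp, smacof_step(Z2, D2, W))
  expect_error(
    joint_stress_step(Z1, Z2, D1, D2, W, W, P, diag(2), lambda = -1),
    "lambda")
})

test_that("perfectly matched configurations keep a zero coupling term", {
  X <- rand_points(5, 2, 42, ids = FALSE)
  D <- unname(pairwise_euclidean(X))
  O <- rotation2(0.5)
  Zp <- X %*% O
  P <- diag(5) / 5
  W <- uniform_weights(5)
  obj0 <- joint_objective(X, Zp, D, D, W, W, P, O, lambda = 1)
  st <- joint_stress_step(X, Zp, D, D, W, W, P, O, lambda = 1)
  obj1 <- joint_objective(st$Z, st$Zp, D, D, W, W, P, O, lambda = 1)
  expect_equal(obj0, 0, tolerance = 1e-20)
  expect_equal(obj1, 0, tolerance = 1e-20)
})

test_that("the joint objective is non-increasing over coupled steps", {
  D1 <- rand_diss(7, 3, 50); D2 <- rand_diss(7, 2, 51)
  W <- uniform_weights(7)
  P <- jointmds:::local_seed(52, {
    M <- matrix(rexp(49), 7)
    M / sum(M)
  })
  O <- rotation2(1.1)
  Z1 <- init_embedding(7, 2, 3); Z2 <- init_embedding(7, 2, 4)
  objs <- joint_objective(Z1, Z2, D1, D2, W, W, P, O, 0.8)
  for (i in 1:20) {
    st <- joint_stress_step(Z1, Z2, D1, D2, W, W, P, O, 0.8)
    Z1 <- st$Z; Z2 <- st$Zp
    objs <- c(objs, joint_objective(Z1, Z2, D1, D2, W, W, P, O, 0.8))
  }
  expect_true(all(diff(objs) <= 1e-12))
})
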
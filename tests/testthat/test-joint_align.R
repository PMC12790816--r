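# Small self-alignment instances: a 2-D Gaussian cloud whose geodesic
# dissimilarity matrix is shared verbatim between the two domains, so the
# true correspondence is the identity.
self_diss <- function(n = 50, seed = 7, k = 5) {
  X <- rand_points(n, 2, seed)
  modality_dissimilarity(X, "geodesic", k = k)
}

test_that("joint MDS aligns two copies of the same dataset", {
  D <- self_diss()
  fit <- joint_mds(D, D, d = 2, lambda = 1, eps = 0.01, max_outer = 30,
                   seed = 3)
  expect_lt(foscttm(fit$Z1, fit$Z2), 0.05)
  # the learned coupling concentrates on the true matches
  expect_gt(sum(diag(fit$P)), 0.25)   # uniform diagonal mass would be 0.02
  expect_lt(max(abs(rowSums(fit$P) - 1 / nrow(D))), 1e-6)
  expect_lt(max(abs(crossprod(fit$O) - diag(2))), 1e-8)
})

test_that("a fixed seed reproduces the full result bitwise", {
  D <- self_diss(30, seed = 8, k = 4)
  f1 <- joint_mds(D, D, d = 2, lambda = 1, eps = 0.05, max_outer = 5,
                  seed = 11)
  f2 <- joint_mds(D, D, d = 2, lambda = 1, eps = 0.05, max_outer = 5,
                  seed = 11)
  expect_identical(f1$Z1, f2$Z1)
  expect_identical(f1$Z2, f2$Z2)
  expect_identical(f1$P, f2$P)
  expect_identical(f1$objective, f2$objective)

  # under random initialization the seed genuinely matters
  r1 <- joint_mds(D, D, d = 2, lambda = 1, eps = 0.05, max_outer = 5,
                  seed = 11, init_method = "random")
  r3 <- joint_mds(D, D, d = 2, lambda = 1, eps = 0.05, max_outer = 5,
                  seed = 12, init_method = "random")
  expect_false(identical(r1$Z1, r3$Z1))
})

test_that("lambda = 0 decouples the embeddings from the transport plan", {
  D1 <- self_diss(20, seed = 9, k = 4)
  D2 <- self_diss(20, seed = 10, k = 4)
  fa <- joint_mds(D1, D2, d = 2, lambda = 0, eps = 0.05, max_outer = 3,
                  seed = 5)
  fb <- joint_mds(D1, D2, d = 2, lambda = 0, eps = 0.5, max_outer = 3,
                  seed = 5)
  # eps changes P but with lambda = 0 the embeddings cannot notice
  expect_false(identical(fa$P, fb$P))
  expect_equal(c(dist(fa$Z1)), c(dist(fb$Z1)), tolerance = 1e-12)
  expect_equal(c(dist(fa$Z2)), c(dist(fb$Z2)), tolerance = 1e-12)
})

test_that("the joint objective trace is non-increasing within slack", {
  D <- self_diss(25, seed = 12, k = 4)
  fit <- joint_mds(D, D, d = 2, lambda = 1, eps = 0.01, max_outer = 10,
                   seed = 2)
  o <- fit$objective
  expect_true(all(diff(o) <= 1e-6 * pmax(abs(o[-length(o)]), 1)))
})

test_that("three identical domains align through the core", {
  D <- self_diss(50, seed = 7, k = 5)
  fit <- joint_mds3(D, D, D, core = 1, d = 2, lambda = 1, eps = 0.01,
                    max_outer = 30, seed = 3)
  ev <- mean(c(foscttm(fit$Z1, fit$Z2), foscttm(fit$Z1, fit$Z3),
               foscttm(fit$Z2, fit$Z3)))
  expect_lt(ev, 0.05)
})

test_that("joint_mds3 validates shapes and honours any core choice", {
  D <- self_diss(15, seed = 13, k = 3)
  Dbig <- self_diss(16, seed = 14, k = 3)
  expect_error(joint_mds3(D, D, Dbig), "equal sample counts")
  expect_error(joint_mds3(D, D, D, core = 4), "core must be")
  for (core in 1:3) {
    fit <- joint_mds3(D, D, D, core = core, d = 2, lambda = 1, eps = 0.05,
                      max_outer = 3, seed = 1)
    expect_identical(fit$core, core)
    expect_identical(ncol(fit$Z1), 2L)
    expect_identical(ncol(fit$Z2), 2L)
    expect_identical(ncol(fit$Z3), 2L)
    expect_identical(nrow(fit$Z3), 15L)
  }
})

test_that("the merge and carry steps apply isometries only", {
  D <- self_diss(25, seed = 15, k = 4)
  fit <- joint_mds3(D, D, D, core = 1, d = 2, lambda = 1, eps = 0.05,
                    max_outer = 5, seed = 4)
  # domain 2 is fit_core_b's second output carried by the merge transform
  expect_equal(c(dist(fit$Z2)), c(dist(fit$fit_core_b$Z2)),
               tolerance = 1e-10)
  # domain 3 is fit_core_c's second output, untouched
  expect_identical(fit$Z3, fit$fit_core_c$Z2)
})

test_that("apply_alignment maps frames as declared", {
  Z <- rand_points(10, 2, 16, ids = FALSE)
  expect_equal(apply_alignment(Z, diag(2), "first"), Z)
  R <- rotation2(0.4)
  expect_equal(c(dist(apply_alignment(Z, R, "first"))), c(dist(Z)),
               tolerance = 1e-12)
  expect_identical(apply_alignment(Z, R, "second"), Z)
  expect_error(apply_alignment(Z, diag(3), "first"), "dimension mismatch")
})

test_that("grid search scores cells and breaks ties lexicographically", {
  X <- rand_points(25, 2, 17)
  E <- pairwise_euclidean(X)
  one <- grid_search(E, E, k_grid = 5, eps_grid = 0.05, lambda_grid = 1,
                     n_seeds = 1, max_outer = 3)
  expect_identical(nrow(one$table), 1L)
  expect_equal(one$best, list(k = 5, eps = 0.05, lambda = 1))

  # a soft plan (huge eps) cannot align as well as a sharp one
  two <- grid_search(E, E, k_grid = 5, eps_grid = c(0.01, 50),
                     lambda_grid = 1, n_seeds = 1, max_outer = 5)
  expect_identical(nrow(two$table), 2L)
  expect_equal(two$best$eps, 0.01)

  # objective criterion with lambda = 0 is eps-independent: exact tie,
  # resolved to the lexicographically smaller cell
  tie <- grid_search(E, E, k_grid = 5, eps_grid = c(0.02, 0.2),
                     lambda_grid = 0, criterion = "objective",
                     n_seeds = 1, max_outer = 2)
  expect_equal(tie$table$score[1], tie$table$score[2], tolerance = 1e-12)
  expect_equal(tie$best$eps, 0.02)

  expect_error(grid_search(E, E, k_grid = numeric(0), eps_grid = 1,
                           lambda_grid = 1), "non-empty")
})
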
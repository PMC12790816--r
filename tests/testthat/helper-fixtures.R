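# Shared fixtures and independent oracles used across the suite.

# deterministic random point cloud with sample IDs
rand_points <- function(n, q, seed, ids = TRUE) {
  X <- jointmds:::local_seed(seed, matrix(rnorm(n * q), n, q))
  if (ids) rownames(X) <- sprintf("s%03d", seq_len(n))
  X
}

rand_diss <- function(n, q = 3, seed = 1) {
  normalize_dissimilarity(pairwise_euclidean(rand_points(n, q, seed)))
}

# O(n^2) brute-force FOSCTTM, straight from the definition
foscttm_brute <- function(Z, Zp) {
  n <- nrow(Z)
  fr <- numeric(0)
  for (i in seq_len(n)) {
    true_d <- sqrt(sum((Z[i, ] - Zp[i, ])^2))
    cnt <- 0
    for (j in seq_len(n)) {
      if (j != i && sqrt(sum((Z[i, ] - Zp[j, ])^2)) < true_d) cnt <- cnt + 1
    }
    fr <- c(fr, cnt / (n - 1))
  }
  for (j in seq_len(n)) {
    true_d <- sqrt(sum((Z[j, ] - Zp[j, ])^2))
    cnt <- 0
    for (i in seq_len(n)) {
      if (i != j && sqrt(sum((Z[i, ] - Zp[j, ])^2)) < true_d) cnt <- cnt + 1
    }
    fr <- c(fr, cnt / (n - 1))
  }
  mean(fr)
}

# exact optimal transport cost over all permutation couplings (uniform
# marginals, n <= 8)
lp_assignment_cost <- function(C) {
  n <- nrow(C)
  perms <- perms_of(seq_len(n))
  best <- Inf
  best_perm <- NULL
  for (k in seq_len(nrow(perms))) {
    cost <- sum(C[cbind(seq_len(n), perms[k, ])]) / n
    if (cost < best) { best <- cost; best_perm <- perms[k, ] }
  }
  list(cost = best, perm = best_perm)
}

perms_of <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# independent exact two-sided Mann-Whitney p: count pairwise wins with
# half-credit for ties (no ranks), enumerate assignments recursively
mw_exact_brute <- function(x, y) {
  u_stat <- function(xx, yy) {
    u <- 0
    for (xi in xx) for (yi in yy)
      u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- u_stat(x, y)
  mid <- n1 * (length(pooled) - n1) / 2
  us <- apply(idx, 2L, function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
}
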
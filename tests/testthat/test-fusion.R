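test_that("full kernel matches the normalisation formula", {
  W <- matrix(c(0, 2, 2,
                2, 0, 2,
                2, 2, 0), 3, 3)
  P <- full_kernel(W)
  expect_equal(P[1, ], c(0.5, 0.25, 0.25))
  expect_equal(rowSums(P), rep(1, 3))

  set.seed(8)
  W <- matrix(runif(36), 6, 6); W <- (W + t(W)) / 2; diag(W) <- 0
  P <- full_kernel(W)
  for (i in 1:6) {
    for (j in 1:6) {
      expected <- if (i == j) 0.5 else W[i, j] / (2 * sum(W[i, -i]))
      expect_equal(P[i, j], expected)
    }
  }
  expect_equal(rowSums(P), rep(1, 6))
})

test_that("an isolated sample is rejected by name", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  dimnames(W) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_error(full_kernel(W), "sample 'c' has no positive affinity")
})

test_that("local kernel keeps the top-k neighbourhood, renormalised", {
  W <- matrix(c(0, 3, 1, 0,
                3, 0, 2, 1,
                1, 2, 0, 2,
                0, 1, 2, 0), 4, 4)
  S <- local_kernel(W, 2)
  expect_equal(S[1, ], c(0, 0.75, 0.25, 0))
  expect_equal(rowSums(S), rep(1, 4))
  expect_true(all(rowSums(S > 0) <= 2))

  # k = n - 1: row-normalised affinity with zero diagonal
  S_all <- local_kernel(W, 3)
  expect_equal(S_all, W / rowSums(W), ignore_attr = TRUE)
  expect_true(all(diag(S_all) == 0))
})

test_that("local kernel matches per-row brute-force top-k selection", {
  set.seed(14)
  W <- matrix(runif(64), 8, 8); W <- (W + t(W)) / 2; diag(W) <- 0
  S <- local_kernel(W, 3)
  for (i in 1:8) {
    w <- W[i, ]; w[i] <- -Inf
    nb <- order(-w, seq_len(8))[1:3]
    expected <- numeric(8)
    expected[nb] <- W[i, nb] / sum(W[i, nb])
    expect_equal(unname(S[i, ]), expected, label = paste("row", i))
  }
})

test_that("a zero neighbourhood zeroes the row with a warning", {
  W <- matrix(0.5, 4, 4); diag(W) <- 0
  W[4, ] <- W[, 4] <- 0   # sample 4 isolated: zero affinity everywhere
  expect_warning(S <- local_kernel(W, 2), "zero neighbourhood affinity")
  expect_equal(S[4, ], rep(0, 4))
  expect_equal(rowSums(S)[1:3], rep(1, 3), ignore_attr = TRUE)
})

test_that("one diffusion sweep equals the explicit matrix products", {
  set.seed(4)
  mk <- function() { W <- matrix(runif(9), 3, 3); W <- (W + t(W)) / 2; diag(W) <- 0; W }
  W1 <- mk(); W2 <- mk()
  fused <- cross_diffuse(list(W1, W2), k = 2, max_iter = 1, renormalize = FALSE)
  P1 <- full_kernel(W1); P2 <- full_kernel(W2)
  S1 <- local_kernel(W1, 2); S2 <- local_kernel(W2, 2)
  P1_new <- S1 %*% P2 %*% t(S1)
  P2_new <- S2 %*% P1 %*% t(S2)
  expected <- (P1_new + P2_new) / 2
  expected <- (expected + t(expected)) / 2
  expect_equal(fused$W, expected, ignore_attr = TRUE)
})

test_that("diffusion rejects degenerate inputs", {
  W <- block_affinity(c(3, 3))
  expect_error(cross_diffuse(list(W), k = 2), "at least two views")
  W2 <- W
  rownames(W2) <- colnames(W2) <- rev(colnames(W))
  expect_error(cross_diffuse(list(W, W2), k = 2), "sample order mismatch")
})

test_that("aligned block structure is preserved through diffusion", {
  W1 <- block_affinity(c(5, 5), between = 0, seed = 2)
  W2 <- block_affinity(c(5, 5), between = 0, seed = 3)
  fused <- cross_diffuse(list(W1, W2), k = 3)
  lab <- attr(W1, "labels")
  off <- sum(fused$W[outer(lab, lab, "!=")])
  expect_lt(off / sum(fused$W), 1e-6)
})

test_that("status matrices stay row-stochastic and the iteration converges", {
  W1 <- block_affinity(c(4, 6), seed = 5)
  W2 <- block_affinity(c(4, 6), seed = 6)
  fused <- cross_diffuse(list(W1, W2), k = 3, max_iter = 30, tol = 1e-6)
  expect_lte(fused$iterations_used, 30)
  expect_lte(fused$history$max_change[fused$iterations_used], 1e-6)
  expect_true(all(fused$history$max_row_dev <= 1e-8))
  for (P in fused$P_list) {
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-10, ignore_attr = TRUE)
    expect_true(all(P >= 0))
  }
})

test_that("permuting sample order permutes the fused network identically", {
  W1 <- block_affinity(c(4, 4), seed = 7)
  W2 <- block_affinity(c(4, 4), seed = 8)
  fused <- cross_diffuse(list(W1, W2), k = 3)
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  fused_p <- cross_diffuse(list(W1[perm, perm], W2[perm, perm]), k = 3)
  expect_equal(fused_p$W, fused$W[perm, perm], tolerance = 1e-12)
})

test_that("identical views fuse to the same partition as a single view", {
  W <- block_affinity(c(5, 5), seed = 9)
  lab <- attr(W, "labels")
  fused2 <- cross_diffuse(list(W, W), k = 3)
  fused3 <- cross_diffuse(list(W, W, W), k = 3)
  cl_direct <- ratio_cut_spectral(W, 2, seed = 1)
  cl2 <- ratio_cut_spectral(fused2, 2, seed = 1)
  cl3 <- ratio_cut_spectral(fused3, 2, seed = 1)
  expect_equal(adjusted_rand_index(cl2, cl_direct), 1)
  expect_equal(adjusted_rand_index(cl3, cl_direct), 1)
  expect_equal(adjusted_rand_index(cl2$labels, lab), 1)
})
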
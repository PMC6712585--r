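test_that("disconnected components are split exactly", {
  W <- matrix(0, 5, 5)
  W[1:2, 1:2] <- 1; W[3:5, 3:5] <- 1
  diag(W) <- 0
  cl <- ratio_cut_spectral(W, 2, seed = 1)
  expect_equal(adjusted_rand_index(cl$labels, c(1, 1, 2, 2, 2)), 1)
  # zero eigenvalue multiplicity equals the component count
  expect_equal(cl$eigenvalues, c(0, 0), tolerance = 1e-10)
})

test_that("the spectral bipartition is enumeration-optimal on a small graph", {
  set.seed(6)
  W <- planted_two_community(6)
  cl <- ratio_cut_spectral(W, 2, seed = 2)
  expect_equal(naive_ratio_cut(W, cl$labels), best_bipartition_objective(W),
               tolerance = 1e-10)
  # package objective agrees with the independent one
  expect_equal(ratio_cut_objective(W, cl$labels), naive_ratio_cut(W, cl$labels))
})

test_that("clustering is equivariant under sample permutation", {
  W <- block_affinity(c(4, 3, 5), seed = 11)
  cl <- ratio_cut_spectral(W, 3, seed = 4)
  perm <- sample(seq_len(12))
  cl_p <- ratio_cut_spectral(W[perm, perm], 3, seed = 4)
  expect_equal(adjusted_rand_index(cl_p$labels, cl$labels[perm]), 1)
})

test_that("cluster count bounds are enforced", {
  W <- block_affinity(c(3, 3))
  expect_error(ratio_cut_spectral(W, 6, seed = 1), "must be smaller than the number of samples")
  expect_error(ratio_cut_spectral(W, 1, seed = 1), "at least 2")
})

test_that("adjusted Rand index handles the canonical cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "differ in length")
})

test_that("ARI matches independent implementations on random partitions", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    ours <- adjusted_rand_index(a, b)
    expect_equal(ours, pair_counting_ari(a, b), tolerance = 1e-12)
    expect_equal(ours, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    # symmetry and label-permutation invariance
    expect_equal(ours, adjusted_rand_index(b, a))
    expect_equal(ours, adjusted_rand_index(5 - a, b))
  }
})

test_that("silhouette of perfectly separated blocks is 1", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1
  diag(W) <- 0
  # within-block similarity 1 -> dissimilarity 0; between -> 1
  expect_equal(silhouette_score(W, c(1, 1, 1, 2, 2, 2)), 1)
  expect_error(silhouette_score(W, rep(1, 6)), "at least two clusters")
})

test_that("silhouette matches the definition-level loop", {
  set.seed(19)
  W <- matrix(runif(100), 10, 10); W <- (W + t(W)) / 2; diag(W) <- 0
  D <- 1 - W / max(W); diag(D) <- 0
  labs <- c(1, 1, 1, 2, 2, 2, 2, 3, 3, 1)
  expect_equal(silhouette_score(W, labs), naive_silhouette(D, labs))
  # singleton convention: the lone member contributes width 0
  labs_singleton <- c(1, 1, 1, 2, 2, 2, 2, 2, 2, 3)
  expect_equal(silhouette_score(W, labs_singleton),
               naive_silhouette(D, labs_singleton))
})

test_that("silhouette-guided selection recovers the planted cluster count", {
  W <- block_affinity(c(8, 8, 8), seed = 23)
  expect_equal(as.integer(select_num_clusters(W, 2, 6, seed = 1)), 3L)
  expect_equal(as.integer(select_num_clusters(W, 4, 4, seed = 1)), 4L)
})

test_that("a flat similarity falls back to the smallest candidate with a warning", {
  W <- matrix(1, 9, 9); diag(W) <- 0
  expect_warning(cc <- select_num_clusters(W, 2, 4, seed = 1),
                 "silhouette profile is flat")
  expect_equal(as.integer(cc), 2L)
})
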
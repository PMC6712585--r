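test_that("the default benchmark has the documented shape", {
  ds <- generate_multiview(synthetic_spec(seed = 2))
  expect_length(ds$views, 2)
  expect_equal(dim(ds$views[[1]]$values), c(500, 90))
  expect_equal(dim(ds$views[[2]]$values), c(300, 90))
  expect_equal(unname(ds$true_labels), rep(1:3, each = 30))
  expect_identical(ds$views[[1]]$sample_ids, ds$views[[2]]$sample_ids)
})

test_that("generation is deterministic given the seed", {
  a <- generate_multiview(synthetic_spec(seed = 77, noise_frac = 0.1))
  b <- generate_multiview(synthetic_spec(seed = 77, noise_frac = 0.1))
  expect_identical(a$views[[1]]$values, b$views[[1]]$values)
  expect_identical(a$views[[2]]$values, b$views[[2]]$values)
  c_ <- generate_multiview(synthetic_spec(seed = 78, noise_frac = 0.1))
  expect_false(identical(a$views[[1]]$values, c_$views[[1]]$values))
})

test_that("a fully indistinguishable cluster pair is rejected", {
  expect_error(synthetic_spec(view_merge_plan = list(list(c(1, 2)), list(c(1, 2)))),
               "clusters 1 and 2 are indistinguishable in every view")
  # distinguishability restored by one separating view is fine
  expect_s3_class(synthetic_spec(view_merge_plan = list(list(c(1, 2)), list(c(2, 3)))),
                  "synthetic_spec")
  expect_error(synthetic_spec(noise_frac = 1.2), "noise_frac")
})

test_that("a view that merges nothing is fully resolvable on clean data", {
  spec <- synthetic_spec(n_per_cluster = 20, n_features = c(200, 150),
                         view_merge_plan = list(list(), list()),
                         noise_frac = 0, seed = 31)
  ds <- generate_multiview(spec)
  expect_equal(single_view_ceiling(ds, 1, seed = 1), 1)
})

test_that("merged boundaries cap single-view accuracy below 0.9", {
  ds <- small_dataset(seed = 41, npc = 20, features = c(200, 150))
  expect_lt(single_view_ceiling(ds, 1, seed = 1), 0.9)
  expect_lt(single_view_ceiling(ds, 2, seed = 1), 0.9)
})

test_that("the ceiling is invariant to sample order", {
  ds <- small_dataset(seed = 51, npc = 10, features = c(80, 60))
  base <- single_view_ceiling(ds, 1, seed = 3)
  perm <- sample(seq_along(ds$true_labels))
  ds_p <- ds
  for (i in seq_along(ds_p$views)) {
    ds_p$views[[i]]$values <- ds_p$views[[i]]$values[, perm]
    ds_p$views[[i]]$sample_ids <- ds_p$views[[i]]$sample_ids[perm]
  }
  ds_p$true_labels <- ds_p$true_labels[perm]
  expect_equal(single_view_ceiling(ds_p, 1, seed = 3), base)
})

test_that("both heterogeneity regimes produce valid datasets", {
  for (het in c("multi-manifold", "single-subspace")) {
    ds <- generate_multiview(synthetic_spec(n_per_cluster = 8,
                                            n_features = c(50, 40),
                                            heterogeneity = het, seed = 13))
    expect_false(any(!is.finite(ds$views[[1]]$values)))
    expect_equal(ncol(ds$views[[1]]$values), 24)
  }
})
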
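# Fixtures and independent oracles shared across the suite.
# Everything is built in code; nothing is read from disk.

# Symmetric nonnegative affinity with planted blocks and light jitter.
block_affinity <- function(sizes, within = 1, between = 0.02, seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  set.seed(seed)
  W <- matrix(between * runif(n * n), n, n)
  for (g in seq_along(sizes)) {
    idx <- lab == g
    W[idx, idx] <- within * (1 + 0.05 * runif(sum(idx)^2))
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- list(sprintf("S%02d", 1:n), sprintf("S%02d", 1:n))
  attr(W, "labels") <- lab
  W
}

# Random two-community weighted graph: the regime with genuine structure.
planted_two_community <- function(n = 8) {
  sz <- sample(2:(n - 2), 1)
  lab <- c(rep(1, sz), rep(2, n - sz))
  A <- ifelse(outer(lab, lab, "=="), runif(n * n, 0.6, 1), runif(n * n, 0, 0.3))
  A <- matrix(A, n, n)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  attr(A, "labels") <- lab
  A
}

# Brute-force Ratio-Cut objective, written independently of the package.
naive_ratio_cut <- function(W, labels) {
  obj <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    obj <- obj + sum(W[idx, !idx, drop = FALSE]) / sum(idx)
  }
  obj
}

# Exhaustive best bipartition objective for small n.
best_bipartition_objective <- function(W) {
  n <- nrow(W)
  best <- Inf
  for (m in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(m))[1:n]
    best <- min(best, naive_ratio_cut(W, lab))
  }
  best
}

# Pair-counting adjusted Rand index, an independent route from the
# contingency-table formula used in the package.
pair_counting_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Definition-level mean silhouette width on a dissimilarity matrix.
naive_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in 1:n) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Union-of-independent-subspaces view: `copies` duplicates of each of
# `n_basis` mutually orthogonal unit vectors.
orthogonal_copies_view <- function(n_basis = 3, copies = 3, h = 12) {
  B <- diag(h)[, seq_len(n_basis), drop = FALSE]
  X <- B[, rep(seq_len(n_basis), each = copies)]
  colnames(X) <- sprintf("S%02d", seq_len(ncol(X)))
  omics_view(X, view_name = "orthogonal")
}

# Small multi-view benchmark used where full scale is not needed.
small_dataset <- function(seed = 1, noise = 0, npc = 15,
                          features = c(120, 90)) {
  generate_multiview(synthetic_spec(n_per_cluster = npc,
                                    n_features = features,
                                    noise_frac = noise, seed = seed))
}
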
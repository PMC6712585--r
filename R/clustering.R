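#' Ratio-Cut spectral clustering
#'
#' Partitions a symmetric nonnegative similarity matrix by the classical
#' Ratio-Cut relaxation: form the unnormalised graph Laplacian
#' `L = D - W` (`D` the diagonal of row sums), embed the samples in the
#' eigenvectors of the `c` smallest eigenvalues, and cluster the embedding
#' with k-means (multiple restarts, all driven by `seed`).
#'
#' @param W a [cross_diffuse()] result or a symmetric nonnegative matrix.
#' @param c number of clusters, `2 <= c <= n - 1`.
#' @param seed integer seed for the k-means restarts; the embedding itself
#'   is deterministic.
#' @param nstart number of k-means restarts (best within-cluster sum of
#'   squares kept).
#' @return An object of class `clustering_result`: integer `labels` in
#'   `1..c` named by sample, `num_clusters`, the `c` smallest Laplacian
#'   `eigenvalues` (ascending), and `seed`.
#' @examples
#' W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 1
#' ratio_cut_spectral(W, 2, seed = 1)$labels
#' @export
ratio_cut_spectral <- function(W, c, seed = 0, nstart = 50) {
  W <- as_affinity_matrix(W)
  check_square_symmetric(W, "W")
  n <- nrow(W)
  c <- as.integer(c)
  if (c < 2) stop("'c' must be at least 2", call. = FALSE)
  if (c >= n) stop(sprintf("'c' (%d) must be smaller than the number of samples (%d)", c, n),
                   call. = FALSE)
  L <- diag(rowSums(W)) - W
  ev <- eigen(L, symmetric = TRUE)
  # eigen() returns eigenvalues in decreasing order; take the c smallest
  V <- ev$vectors[, n:(n - c + 1), drop = FALSE]
  vals <- rev(ev$values)[seq_len(c)]
  km <- with_seed(seed, kmeans(V, centers = c, nstart = nstart, iter.max = 100))
  labels <- as.integer(km$cluster)
  names(labels) <- colnames(W)
  structure(list(labels = labels, num_clusters = c, eigenvalues = vals,
                 seed = seed),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %d samples in %d clusters (sizes: %s)\n",
              length(x$labels), x$num_clusters,
              paste(tabulate(x$labels, x$num_clusters), collapse = ", ")))
  invisible(x)
}

#' Ratio-Cut objective of a partition
#'
#' `sum_g cut(C_g, complement) / |C_g|`; smaller is better.  Exposed mainly
#' for inspection and benchmarking of partitions.
#'
#' @param W symmetric nonnegative similarity matrix.
#' @param labels partition of the samples.
#' @return A single number.
#' @export
ratio_cut_objective <- function(W, labels) {
  W <- as_affinity_matrix(W)
  if (length(labels) != nrow(W)) stop("'labels' length must equal nrow(W)", call. = FALSE)
  obj <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    obj <- obj + sum(W[idx, !idx, drop = FALSE]) / sum(idx)
  }
  obj
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie form,
#' computed from the contingency table).  1 for identical partitions, about
#' 0 for independent ones; can be negative for partitions that agree less
#' than chance.
#'
#' @param a,b label vectors of equal length (any label coding).
#' @return A number in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand_index <- function(a, b) {
  if (inherits(a, "clustering_result")) a <- a$labels
  if (inherits(b, "clustering_result")) b <- b$labels
  if (length(a) != length(b)) {
    stop(sprintf("label vectors differ in length (%d vs %d)", length(a), length(b)),
         call. = FALSE)
  }
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  expected <- sum_i * sum_j / total
  denom <- (sum_i + sum_j) / 2 - expected
  if (abs(denom) < .Machine$double.eps) {
    # both partitions trivial (all-singletons or single cluster): identical
    # co-membership means perfect agreement
    return(if (sum_ij == expected) 1 else 0)
  }
  (sum_ij - expected) / denom
}

#' Mean silhouette width of a partition on a similarity network
#'
#' Converts the similarity matrix to a dissimilarity
#' `d(i, j) = 1 - W(i, j) / max(W)` and returns the mean silhouette width
#' of the partition (members of singleton clusters contribute width 0, the
#' usual convention).
#'
#' @param W symmetric nonnegative similarity matrix.
#' @param labels partition with at least two clusters.
#' @return A number in `[-1, 1]`.
#' @export
silhouette_score <- function(W, labels) {
  W <- as_affinity_matrix(W)
  check_square_symmetric(W, "W")
  if (inherits(labels, "clustering_result")) labels <- labels$labels
  if (length(labels) != nrow(W)) stop("'labels' length must equal nrow(W)", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("silhouette needs at least two clusters", call. = FALSE)
  }
  mx <- max(W)
  if (mx <= 0) stop("'W' is identically zero; silhouette is undefined", call. = FALSE)
  D <- 1 - W / mx
  diag(D) <- 0
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Choose the number of clusters by silhouette
#'
#' Runs [ratio_cut_spectral()] for each candidate `c` and returns the one
#' with the largest mean silhouette width on `W`; ties (and a completely
#' flat silhouette profile) go to the smallest candidate.
#'
#' @param W symmetric nonnegative similarity matrix.
#' @param c_min,c_max candidate range, `2 <= c_min <= c_max <= n - 1`.
#' @param seed seed forwarded to each spectral clustering call.
#' @return The selected number of clusters (integer, with the per-candidate
#'   scores attached as attribute `"scores"`).
#' @export
select_num_clusters <- function(W, c_min = 2, c_max = 8, seed = 0) {
  W <- as_affinity_matrix(W)
  c_min <- as.integer(c_min); c_max <- as.integer(c_max)
  n <- nrow(W)
  if (c_min < 2 || c_max < c_min || c_max > n - 1) {
    stop(sprintf("need 2 <= c_min <= c_max <= n - 1 (got %d..%d, n = %d)", c_min, c_max, n),
         call. = FALSE)
  }
  cands <- c_min:c_max
  scores <- vapply(cands, function(cc) {
    silhouette_score(W, ratio_cut_spectral(W, cc, seed = seed))
  }, numeric(1))
  if (length(cands) > 1 && diff(range(scores)) < 1e-12) {
    warning("silhouette profile is flat across all candidates; returning the smallest",
            call. = FALSE)
  }
  best <- cands[which.max(scores)]   # which.max takes the first, i.e. smallest c
  attr(best, "scores") <- setNames(scores, cands)
  best
}
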
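#' Specification of a synthetic multi-view benchmark
#'
#' Describes a planted-cluster multi-omics benchmark in which each view can
#' resolve only a subset of the cluster boundaries: clusters listed
#' together in a view's *merge plan* are drawn so that this view carries no
#' usable boundary between them, while other views do.  The default mirrors
#' a two-view, 90-sample design with three clusters of 30 where view 1
#' cannot separate clusters 2 and 3 and view 2 cannot separate clusters 1
#' and 2 — so only integration across views can recover all three groups.
#'
#' Two heterogeneity regimes are available.  With `"single-subspace"`
#' (weak heterogeneity) every group of clusters a view cannot tell apart is
#' drawn from one common low-dimensional linear subspace.  With
#' `"multi-manifold"` (strong heterogeneity, the default) each cluster lies
#' on its own randomly curved low-dimensional surface, with merged
#' clusters' surfaces interleaved inside a shared subspace: pairwise
#' Euclidean proximity then carries almost no information about cluster
#' membership within a merged group, while the subspace structure that the
#' representation step exploits is preserved.
#'
#' Distinguishable groups additionally receive a spatial offset
#' (`group_offset`) so that boundaries a view *does* resolve are visible
#' both to subspace representation and to plain distance-based clustering,
#' as in real data where distinct molecular programmes also shift the mean
#' profile.
#'
#' @param n_per_cluster samples per planted cluster.
#' @param n_clusters number of planted clusters.
#' @param view_merge_plan one element per view: a list of integer vectors,
#'   each vector a group of cluster indices that view cannot distinguish.
#'   Clusters not mentioned form their own group.  Every pair of clusters
#'   must be distinguishable in at least one view.
#' @param n_features integer vector, features per view.
#' @param heterogeneity `"multi-manifold"` or `"single-subspace"`.
#' @param noise_frac additive Gaussian noise with standard deviation equal
#'   to `noise_frac` times the signal standard deviation, in `[0, 1]`.
#' @param seed integer; the generator is fully deterministic given the seed.
#' @param group_offset distance between the centres of distinguishable
#'   groups, in units of the within-group signal scale.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_cluster = 30, n_clusters = 3,
                           view_merge_plan = list(list(c(2, 3)), list(c(1, 2))),
                           n_features = c(500, 300),
                           heterogeneity = c("multi-manifold", "single-subspace"),
                           noise_frac = 0, seed = 1, group_offset = 1.5) {
  heterogeneity <- match.arg(heterogeneity)
  n_per_cluster <- as.integer(n_per_cluster)
  n_clusters <- as.integer(n_clusters)
  if (n_per_cluster < 2 || n_clusters < 2) {
    stop("need at least 2 clusters with at least 2 samples each", call. = FALSE)
  }
  if (length(view_merge_plan) != length(n_features)) {
    stop("'view_merge_plan' and 'n_features' must have one entry per view", call. = FALSE)
  }
  if (noise_frac < 0 || noise_frac > 1) {
    stop("'noise_frac' must lie in [0, 1]", call. = FALSE)
  }
  plan <- lapply(view_merge_plan, function(v) lapply(v, as.integer))
  for (v in seq_along(plan)) {
    ids <- unlist(plan[[v]])
    if (length(ids) && (any(ids < 1) || any(ids > n_clusters) || anyDuplicated(ids))) {
      stop(sprintf("invalid merge plan for view %d", v), call. = FALSE)
    }
  }
  # feasibility: every cluster pair separated by at least one view
  for (a in seq_len(n_clusters - 1)) {
    for (b in (a + 1):n_clusters) {
      merged_everywhere <- all(vapply(plan, function(v) {
        any(vapply(v, function(g) a %in% g && b %in% g, logical(1)))
      }, logical(1)))
      if (merged_everywhere) {
        stop(sprintf("clusters %d and %d are indistinguishable in every view; no method could separate them", a, b),
             call. = FALSE)
      }
    }
  }
  structure(list(n_per_cluster = n_per_cluster, n_clusters = n_clusters,
                 view_merge_plan = plan, n_features = as.integer(n_features),
                 heterogeneity = heterogeneity, noise_frac = noise_frac,
                 seed = as.integer(seed), group_offset = group_offset),
            class = "synthetic_spec")
}

# Partition the clusters of one view into indistinguishable groups.
merge_groups <- function(plan_view, n_clusters) {
  merged <- unlist(plan_view)
  groups <- plan_view
  for (cl in setdiff(seq_len(n_clusters), merged)) groups <- c(groups, list(cl))
  groups[order(vapply(groups, min, integer(1)))]
}

# Dimensions of the per-group latent spaces (see the methods vignette).
.subspace_dim_single <- 3L   # linear subspace, loadings on its unit sphere
.subspace_dim_multi <- 6L    # ambient subspace holding the curved surfaces

# One view's signal + noise matrix.  Assumes the RNG state is already set.
generate_view_matrix <- function(spec, v, labels) {
  h <- spec$n_features[v]
  n <- length(labels)
  groups <- merge_groups(spec$view_merge_plan[[v]], spec$n_clusters)
  X <- matrix(0, h, n)
  for (g in groups) {
    centre <- spec$group_offset * unit_columns(matrix(rnorm(h), h, 1))
    if (spec$heterogeneity == "single-subspace") {
      d <- .subspace_dim_single
      B <- random_orthonormal(h, d)
      idx <- which(labels %in% g)
      C <- unit_columns(matrix(rnorm(d * length(idx)), d, length(idx)))
      X[, idx] <- as.vector(centre) + B %*% C
    } else {
      d <- .subspace_dim_multi
      B <- random_orthonormal(h, d)      # shared by all clusters in the group
      for (cl in g) {
        idx <- which(labels == cl)
        ng <- length(idx)
        # randomly curved 2-surface: quadratic embedding of a Gaussian sheet,
        # radially normalised so merged clusters interleave on the unit
        # sphere of the shared subspace
        A <- matrix(rnorm(d * 2), d, 2)
        Q <- matrix(rnorm(d * 3), d, 3)
        t1 <- rnorm(ng); t2 <- rnorm(ng)
        C <- A %*% rbind(t1, t2) + Q %*% rbind(t1^2, t2^2, t1 * t2)
        X[, idx] <- as.vector(centre) + B %*% unit_columns(C)
      }
    }
  }
  if (spec$noise_frac > 0) {
    X <- X + spec$noise_frac * sd(X) * matrix(rnorm(h * n), h, n)
  }
  X
}

#' Generate a synthetic multi-view dataset
#'
#' Draws the benchmark described by a [synthetic_spec()]: one
#' features x samples matrix per view over a shared sample set, plus the
#' planted cluster labels.  Identical specs (including the seed) produce
#' bitwise-identical datasets.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `multiview_dataset`: `views` (list of
#'   [omics_view()]), `true_labels` (integer vector named by sample) and
#'   the `spec`.
#' @examples
#' ds <- generate_multiview(synthetic_spec(n_per_cluster = 10,
#'                                         n_features = c(60, 40), seed = 7))
#' sapply(ds$views, function(v) dim(v$values))
#' table(ds$true_labels)
#' @export
generate_multiview <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_per_cluster * spec$n_clusters
  labels <- rep(seq_len(spec$n_clusters), each = spec$n_per_cluster)
  sample_ids <- sprintf("S%03d", seq_len(n))
  names(labels) <- sample_ids
  views <- with_seed(spec$seed, {
    lapply(seq_along(spec$n_features), function(v) {
      X <- generate_view_matrix(spec, v, labels)
      rownames(X) <- sprintf("V%d_F%04d", v, seq_len(nrow(X)))
      colnames(X) <- sample_ids
      omics_view(X, view_name = sprintf("view%d", v))
    })
  })
  structure(list(views = views, true_labels = labels, spec = spec),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("<multiview_dataset> %d samples, %d planted clusters, %d views (%s), noise %.0f%%\n",
              length(x$true_labels), x$spec$n_clusters, length(x$views),
              x$spec$heterogeneity, 100 * x$spec$noise_frac))
  invisible(x)
}

#' Gaussian-kernel affinity of a view
#'
#' `exp(-d^2 / (2 sigma^2))` on pairwise Euclidean distances with
#' `sigma` the median pairwise distance; diagonal zeroed.  This is the
#' plain distance-based similarity used as the single-view baseline.
#'
#' @param view an [omics_view()] or features x samples matrix.
#' @return Symmetric nonnegative n x n matrix.
#' @export
gaussian_affinity <- function(view) {
  X <- if (inherits(view, "omics_view")) view$values else view
  D <- as.matrix(dist(t(X)))
  sigma <- median(D[upper.tri(D)])
  if (sigma <= 0) sigma <- 1
  W <- exp(-D^2 / (2 * sigma^2))
  diag(W) <- 0
  W
}

#' Best-effort clustering accuracy of a single view
#'
#' Clusters one view alone — Gaussian-kernel affinity of the raw
#' measurements followed by Ratio-Cut spectral clustering into the planted
#' number of clusters — and returns the adjusted Rand index against the
#' planted labels.  On the default benchmark this quantifies how much of
#' the structure is invisible to any single data type.
#'
#' @param dataset a [generate_multiview()] result.
#' @param view_index which view to evaluate.
#' @param seed seed for the spectral clustering.
#' @return A single ARI value.
#' @export
single_view_ceiling <- function(dataset, view_index, seed = 0) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  if (view_index < 1 || view_index > length(dataset$views)) {
    stop("'view_index' out of range", call. = FALSE)
  }
  W <- gaussian_affinity(dataset$views[[view_index]])
  cl <- ratio_cut_spectral(W, dataset$spec$n_clusters, seed = seed)
  adjusted_rand_index(cl$labels, dataset$true_labels)
}
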
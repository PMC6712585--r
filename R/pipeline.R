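#' Run the full multi-view subspace clustering pipeline
#'
#' Orchestrates the three stages on two or more views of the same samples:
#' per-view locality-constrained low-rank representation
#' ([knn_adjacency()], [solve_lrr()], [affinity_from_representation()]),
#' cross-view diffusion ([cross_diffuse()]), and Ratio-Cut spectral
#' clustering of the fused network ([ratio_cut_spectral()]).
#'
#' Views may be given as [omics_view()] objects, plain feature x sample
#' matrices, or file paths (read with [read_view()]).  Samples are
#' reconciled by identifier: views are reordered to the first view's order
#' and a differing sample *set* is an error.
#'
#' @param views list of views (see above); a [generate_multiview()] result
#'   is also accepted.
#' @param k_neighbors neighbourhood size for both the representation
#'   support and the diffusion kernels; default `max(3, floor(n / 10))`.
#' @param lambda error-term weight of the representation model.
#' @param num_clusters integer, or `"auto"` to pick the silhouette-best
#'   value in `2..min(8, n - 1)` via [select_num_clusters()].
#' @param seed seed for the clustering (and, for `"auto"`, the selection).
#' @param zscore standardise each feature within each view first.
#' @param solver a [solver_config()] for the representation stage.
#' @param fusion_iters,fusion_tol diffusion stopping controls.
#' @param renormalize keep the diffusion row-stochastic (see
#'   [cross_diffuse()]).
#' @param out_dir if non-`NULL`, write labels, the fused network, the
#'   resolved configuration and the solver residual summaries there.
#' @param dump_intermediates with `out_dir`, also write each view's
#'   coefficient matrix `Z` and affinity `W`.
#' @param verbose print one summary line per stage.
#' @return An object of class `msca_result`: `clustering`
#'   (a `clustering_result`), `fused` (a `fused_network`), per-view
#'   `solutions` and `affinities`, and the resolved `config`.
#' @examples
#' \donttest{
#' ds <- generate_multiview(synthetic_spec(n_per_cluster = 12,
#'                                         n_features = c(80, 60), seed = 3))
#' fit <- run_msca(ds, num_clusters = 3, seed = 1)
#' adjusted_rand_index(fit$clustering, ds$true_labels)
#' }
#' @export
run_msca <- function(views, k_neighbors = NULL, lambda = 0.5,
                     num_clusters = 3, seed = 0, zscore = TRUE,
                     solver = solver_config(lambda = lambda),
                     fusion_iters = 30, fusion_tol = 1e-6,
                     renormalize = TRUE, out_dir = NULL,
                     dump_intermediates = FALSE, verbose = FALSE) {
  if (inherits(views, "multiview_dataset")) views <- views$views
  if (!is.list(views) || length(views) < 2) {
    stop("'views' must be a list of at least two views", call. = FALSE)
  }
  views <- lapply(seq_along(views), function(i) {
    v <- views[[i]]
    if (is.character(v)) v <- read_view(v)
    if (is.matrix(v)) v <- omics_view(v, view_name = sprintf("view%d", i))
    if (!inherits(v, "omics_view")) stop(sprintf("view %d is not an omics view", i), call. = FALSE)
    v
  })
  views <- align_views(views)
  n <- length(views[[1]]$sample_ids)
  if (is.null(k_neighbors)) k_neighbors <- max(3L, floor(n / 10))
  solver$lambda <- lambda

  prepped <- if (zscore) lapply(views, zscore_view) else views
  solutions <- vector("list", length(views))
  affinities <- vector("list", length(views))
  for (i in seq_along(prepped)) {
    sup <- knn_adjacency(prepped[[i]], k_neighbors)
    sol <- tryCatch(solve_lrr(prepped[[i]], sup, solver),
                    error = function(e) {
                      stop(sprintf("representation stage failed for view '%s': %s",
                                   prepped[[i]]$view_name, conditionMessage(e)), call. = FALSE)
                    })
    if (verbose) {
      message(sprintf("[%s] representation: %d iterations, converged = %s",
                      prepped[[i]]$view_name, sol$iterations, sol$converged))
    }
    solutions[[i]] <- sol
    affinities[[i]] <- affinity_from_representation(sol)
  }
  fused <- cross_diffuse(affinities, k = k_neighbors, max_iter = fusion_iters,
                         tol = fusion_tol, renormalize = renormalize)
  if (verbose) {
    message(sprintf("[fusion] %d sweeps, last change %.2e", fused$iterations_used,
                    fused$history$max_change[fused$iterations_used]))
  }
  auto <- identical(num_clusters, "auto")
  if (auto) {
    num_clusters <- select_num_clusters(fused$W, 2, min(8L, n - 1L), seed = seed)
  }
  clustering <- ratio_cut_spectral(fused, as.integer(num_clusters), seed = seed)
  if (verbose) {
    message(sprintf("[clustering] %d clusters, sizes %s", clustering$num_clusters,
                    paste(tabulate(clustering$labels), collapse = ", ")))
  }
  config <- list(view_names = vapply(views, `[[`, "", "view_name"),
                 n_samples = n, k_neighbors = as.integer(k_neighbors),
                 lambda = lambda,
                 num_clusters = as.integer(num_clusters),
                 num_clusters_auto = auto,
                 seed = as.integer(seed), zscore = zscore,
                 solver = unclass(solver),
                 fusion_iters = as.integer(fusion_iters),
                 fusion_tol = fusion_tol, renormalize = renormalize)
  result <- structure(list(clustering = clustering, fused = fused,
                           solutions = solutions, affinities = affinities,
                           config = config),
                      class = "msca_result")
  if (!is.null(out_dir)) write_msca_outputs(result, out_dir, dump_intermediates)
  result
}

#' @export
print.msca_result <- function(x, ...) {
  cat(sprintf("<msca_result> %d views fused over %d samples\n",
              length(x$affinities), x$config$n_samples))
  print(x$clustering)
  invisible(x)
}

# Reorder every view to the first view's sample order; differing sample
# sets are an error (identifier-based, never positional).
align_views <- function(views) {
  ref <- views[[1]]$sample_ids
  for (i in seq_along(views)[-1]) {
    ids <- views[[i]]$sample_ids
    if (!setequal(ids, ref)) {
      missing <- setdiff(ref, ids)
      extra <- setdiff(ids, ref)
      stop(sprintf("view '%s' covers a different sample set than view '%s'%s%s",
                   views[[i]]$view_name, views[[1]]$view_name,
                   if (length(missing)) paste0("; missing: ", paste(utils::head(missing, 3), collapse = ", ")) else "",
                   if (length(extra)) paste0("; extra: ", paste(utils::head(extra, 3), collapse = ", ")) else ""),
           call. = FALSE)
    }
    if (!identical(ids, ref)) {
      ord <- match(ref, ids)
      views[[i]]$values <- views[[i]]$values[, ord, drop = FALSE]
      views[[i]]$sample_ids <- ref
    }
  }
  views
}

write_msca_outputs <- function(result, out_dir, dump_intermediates = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_labels_tsv(result$clustering, file.path(out_dir, "labels.tsv"))
  write_matrix_tsv(result$fused$W, file.path(out_dir, "fused_network.tsv"),
                   id_header = "sample_id")
  yaml::write_yaml(result$config, file.path(out_dir, "config.yaml"))
  res_lines <- unlist(lapply(seq_along(result$solutions), function(i) {
    s <- result$solutions[[i]]
    r <- s$residuals[s$iterations, ]
    sprintf("view %d (%s): %d iterations, converged=%s, residuals reconstruction=%.3e affine=%.3e gap=%.3e",
            i, result$config$view_names[i], s$iterations, s$converged, r[1], r[2], r[3])
  }))
  writeLines(res_lines, file.path(out_dir, "solver_summary.log"))
  if (dump_intermediates) {
    for (i in seq_along(result$solutions)) {
      write_matrix_tsv(result$solutions[[i]]$Z,
                       file.path(out_dir, sprintf("Z_view%d.tsv", i)),
                       id_header = "sample_id")
      write_matrix_tsv(result$affinities[[i]],
                       file.path(out_dir, sprintf("W_view%d.tsv", i)),
                       id_header = "sample_id")
    }
  }
  invisible(out_dir)
}

#' Read a pipeline configuration file
#'
#' YAML key-value file whose keys mirror the arguments of [run_msca()]
#' (`views`, `k_neighbors`, `lambda`, `num_clusters`, `seed`, `zscore`,
#' `fusion_iters`, `fusion_tol`, `renormalize`, `out_dir`).  Used by the
#' command-line wrapper, where flags override file values.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a key-value mapping", call. = FALSE)
  cfg
}
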
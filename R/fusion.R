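#' Full-graph status matrix of an affinity matrix
#'
#' Normalises an affinity matrix into a row-stochastic "status" matrix that
#' keeps the full similarity profile of every sample while removing
#' scale differences between views: half the probability mass stays on the
#' sample itself and the other half is spread over all other samples in
#' proportion to their affinity,
#' `P[i, j] = W[i, j] / (2 * sum_{k != i} W[i, k])` for `j != i` and
#' `P[i, i] = 1/2`.
#'
#' @param W symmetric nonnegative affinity matrix.
#' @return Row-stochastic matrix of the same dimension.
#' @export
full_kernel <- function(W) {
  W <- as_affinity_matrix(W)
  check_square_symmetric(W, "W")
  n <- nrow(W)
  off <- rowSums(W) - diag(W)
  if (any(off <= 0)) {
    i <- which(off <= 0)[1]
    id <- if (!is.null(rownames(W))) rownames(W)[i] else as.character(i)
    stop(sprintf("sample '%s' has no positive affinity to any other sample; cannot normalise an isolated row", id),
         call. = FALSE)
  }
  P <- W / (2 * off)
  diag(P) <- 0.5
  P
}

#' Local kernel (K-nearest-neighbour restricted) of an affinity matrix
#'
#' Row `i` keeps only the `k` samples with largest affinity to `i` (self
#' excluded, ties broken by ascending index) and renormalises them to sum
#' to one.  The local kernel is the diffusion operator: it propagates
#' similarity only through each sample's trusted neighbourhood, which makes
#' the cross-view diffusion robust to the weak long-range affinities.
#'
#' Rows whose neighbourhood affinities sum to zero are set to zero with a
#' warning rather than an error, since a sample disconnected in one view
#' can still receive similarity through the other views.
#'
#' @param W symmetric nonnegative affinity matrix.
#' @param k neighbourhood size, `1 <= k <= n - 1`.
#' @return Matrix with at most `k` nonzeros per row; rows with a nonempty
#'   neighbourhood sum to one.
#' @export
local_kernel <- function(W, k) {
  W <- as_affinity_matrix(W)
  check_square_symmetric(W, "W")
  n <- nrow(W)
  k <- as.integer(k)
  if (k < 1 || k >= n) {
    stop(sprintf("'k' (%d) must be in [1, n - 1] with n = %d", k, n), call. = FALSE)
  }
  S <- matrix(0, n, n, dimnames = dimnames(W))
  idx <- seq_len(n)
  zero_rows <- character(0)
  for (i in idx) {
    ord <- order(-W[i, ], idx)
    ord <- ord[ord != i][seq_len(k)]
    s <- sum(W[i, ord])
    if (s > 0) {
      S[i, ord] <- W[i, ord] / s
    } else {
      zero_rows <- c(zero_rows,
                     if (!is.null(rownames(W))) rownames(W)[i] else as.character(i))
    }
  }
  if (length(zero_rows)) {
    warning(sprintf("local_kernel: zero neighbourhood affinity for sample(s) %s; their rows are set to 0",
                    paste(zero_rows, collapse = ", ")), call. = FALSE)
  }
  S
}

#' Cross-view graph diffusion to a fused sample network
#'
#' Initialises each view's status matrix `P_i` with [full_kernel()] and its
#' diffusion operator `S_i` with [local_kernel()], then iterates, for every
#' view simultaneously,
#' \deqn{P^{i}_{t+1} = S^i \left(\frac{\sum_{k \ne i} P^k_t}{m - 1}\right) (S^i)^\top,}
#' i.e. each view's global similarity profile is replaced by the average of
#' the *other* views' profiles, propagated through this view's local
#' neighbourhoods.  After every sweep each `P_i` is symmetrised and
#' re-normalised with the [full_kernel()] transform so the iteration stays
#' row-stochastic (set `renormalize = FALSE` for the literal un-normalised
#' update).  The iteration stops when the largest elementwise change across
#' views drops below `tol`, and the fused network is the across-view mean of
#' the final status matrices, symmetrised.
#'
#' @param W_list list of two or more affinity matrices over the same samples
#'   in the same order (dimnames are checked when present).
#' @param k neighbourhood size for the local kernels.
#' @param max_iter maximum number of diffusion sweeps.
#' @param tol stopping threshold on the max elementwise change.
#' @param renormalize re-apply the status normalisation after each sweep
#'   (recommended; keeps every `P_i` exactly row-stochastic).
#' @return An object of class `fused_network`: fused matrix `W`,
#'   `sample_ids`, `iterations_used`, per-iteration `history`
#'   (`max_change`, `max_row_dev` = largest `|row sum - 1|` across views),
#'   final per-view status matrices `P_list` and kernels `S_list`.
#' @export
cross_diffuse <- function(W_list, k, max_iter = 30, tol = 1e-6,
                          renormalize = TRUE) {
  m <- length(W_list)
  if (m < 2) {
    stop("cross-view diffusion needs at least two views (the across-view average over m - 1 views is undefined for m = 1)",
         call. = FALSE)
  }
  W_list <- lapply(W_list, as_affinity_matrix)
  ids <- colnames(W_list[[1]])
  n <- ncol(W_list[[1]])
  for (i in seq_along(W_list)) {
    if (ncol(W_list[[i]]) != n) {
      stop("all views must cover the same number of samples", call. = FALSE)
    }
    idsi <- colnames(W_list[[i]])
    if (!is.null(ids) && !is.null(idsi) && !identical(ids, idsi)) {
      stop(sprintf("sample order mismatch between view 1 and view %d", i), call. = FALSE)
    }
  }
  P <- lapply(W_list, full_kernel)
  S <- lapply(W_list, local_kernel, k = k)
  history <- matrix(NA_real_, max_iter, 2,
                    dimnames = list(NULL, c("max_change", "max_row_dev")))
  t_used <- 0L
  for (t in seq_len(max_iter)) {
    P_new <- vector("list", m)
    for (i in seq_len(m)) {
      avg <- Reduce(`+`, P[-i]) / (m - 1)
      Pi <- S[[i]] %*% avg %*% t(S[[i]])
      P_new[[i]] <- if (renormalize) full_kernel((Pi + t(Pi)) / 2) else Pi
    }
    change <- max(mapply(function(a, b) max_abs(a - b), P_new, P))
    row_dev <- max(vapply(P_new, function(p) max_abs(rowSums(p) - 1), numeric(1)))
    t_used <- t
    history[t, ] <- c(change, row_dev)
    P <- P_new
    if (change <= tol) break
  }
  W_hash <- Reduce(`+`, P) / m
  W_hash <- (W_hash + t(W_hash)) / 2
  if (!is.null(ids)) dimnames(W_hash) <- list(ids, ids)
  structure(list(W = W_hash, sample_ids = ids, iterations_used = t_used,
                 history = as.data.frame(history[seq_len(t_used), , drop = FALSE]),
                 P_list = P, S_list = S, renormalized = renormalize),
            class = "fused_network")
}

#' @export
print.fused_network <- function(x, ...) {
  cat(sprintf("<fused_network> %d samples, %d views, %d diffusion sweeps (last change %.2e)\n",
              nrow(x$W), length(x$P_list), x$iterations_used,
              x$history$max_change[x$iterations_used]))
  invisible(x)
}
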
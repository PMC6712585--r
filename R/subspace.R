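#' K-nearest-neighbour support for the representation coefficients
#'
#' Builds the set of index pairs allowed to carry nonzero representation
#' coefficients: sample `j` may only be represented by the `k` samples
#' nearest to it in Euclidean distance (self excluded).  Restricting the
#' coefficient support to local neighbourhoods is what lets the low-rank
#' representation follow curved manifolds instead of only global linear
#' subspaces.
#'
#' Distance ties are broken by ascending sample index so that the support is
#' reproducible, including for duplicated sample coordinates.
#'
#' @param view an [omics_view()] or a numeric features x samples matrix.
#' @param k number of neighbours per sample, `1 <= k <= n - 1`.
#' @return An object of class `neighbor_support`: a list with `support`
#'   (n x n logical matrix, entry `[i, j]` is `TRUE` when sample `i` may
#'   represent sample `j`), `k` and `sample_ids`.
#' @examples
#' v <- omics_view(matrix(c(0, 1, 10), 1, 3,
#'                        dimnames = list(NULL, c("a", "b", "c"))))
#' knn_adjacency(v, 1)$support
#' @export
knn_adjacency <- function(view, k) {
  X <- if (inherits(view, "omics_view")) view$values else view
  n <- ncol(X)
  k <- as.integer(k)
  if (k < 1) stop("'k' must be at least 1", call. = FALSE)
  if (k >= n) {
    stop(sprintf("'k' (%d) must be smaller than the number of samples (%d)", k, n),
         call. = FALSE)
  }
  D <- as.matrix(dist(t(X)))
  support <- matrix(FALSE, n, n)
  idx <- seq_len(n)
  for (j in idx) {
    ord <- order(D[, j], idx)          # ties resolved by lower index
    ord <- ord[ord != j][seq_len(k)]
    support[ord, j] <- TRUE
  }
  ids <- colnames(X)
  if (!is.null(ids)) dimnames(support) <- list(ids, ids)
  structure(list(support = support, k = k, sample_ids = ids),
            class = "neighbor_support")
}

#' @export
print.neighbor_support <- function(x, ...) {
  cat(sprintf("<neighbor_support> %d samples, k = %d\n",
              ncol(x$support), x$k))
  invisible(x)
}

#' Singular-value thresholding
#'
#' Proximal operator of the nuclear norm: for `M = U diag(s) V'` returns
#' `U diag(max(s - tau, 0)) V'`, the minimiser of
#' `||J||_* + (1 / (2 tau)) ||M - J||_F^2` when `tau > 0`.  This is the
#' closed-form update of the low-rank auxiliary variable in the
#' representation solver.
#'
#' @param M numeric matrix.
#' @param tau nonnegative threshold applied to the singular values.
#' @return Matrix of the same dimension as `M`.
#' @examples
#' svt(diag(c(3, 1)), 1)   # diag(2, 0)
#' @export
svt <- function(M, tau) {
  stopifnot_scalar_number(tau, "tau", positive = FALSE)
  if (tau < 0) stop("'tau' must be nonnegative", call. = FALSE)
  if (all(M == 0)) return(M)
  s <- svd(M)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  out <- s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
  dimnames(out) <- dimnames(M)
  out
}

#' Column-wise l2,1 shrinkage
#'
#' Proximal operator of the l2,1 norm (sum of column Euclidean norms):
#' column `j` of the output is `max(0, 1 - tau / ||m_j||) * m_j`.  Columns
#' with norm at most `tau` are zeroed, which is what makes the error term of
#' the representation model sample-sparse: whole outlying samples are
#' absorbed into `E` rather than individual entries.
#'
#' @param M numeric matrix (features x samples).
#' @param tau nonnegative threshold on column norms.
#' @return Matrix of the same dimension as `M`.
#' @export
l21_shrink <- function(M, tau) {
  stopifnot_scalar_number(tau, "tau", positive = FALSE)
  if (tau < 0) stop("'tau' must be nonnegative", call. = FALSE)
  nrm <- sqrt(colSums(M^2))
  scale <- pmax(0, 1 - tau / pmax(nrm, .Machine$double.eps))
  out <- sweep(M, 2, scale, `*`)
  dimnames(out) <- dimnames(M)
  out
}

#' Solver configuration for the representation problem
#'
#' @param lambda balance between the nuclear-norm term and the l2,1 error
#'   term. The method is insensitive to `lambda` over roughly `[0.1, 1]`.
#' @param mu_init initial value of the augmented-Lagrangian penalty.
#' @param mu_growth geometric growth factor of the penalty per iteration.
#' @param mu_max cap on the penalty.
#' @param max_iter iteration budget.
#' @param tol convergence tolerance on the max-norm of the three constraint
#'   residuals.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(lambda = 0.5, mu_init = 1e-2, mu_growth = 1.1,
                          mu_max = 1e10, max_iter = 500, tol = 1e-6) {
  stopifnot_scalar_number(lambda, "lambda")
  stopifnot_scalar_number(mu_init, "mu_init")
  stopifnot_scalar_number(mu_max, "mu_max")
  stopifnot_scalar_number(tol, "tol")
  if (mu_growth <= 1) stop("'mu_growth' must exceed 1", call. = FALSE)
  if (mu_init > mu_max) stop("'mu_init' must not exceed 'mu_max'", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1) stop("'max_iter' must be positive", call. = FALSE)
  structure(list(lambda = lambda, mu_init = mu_init, mu_growth = mu_growth,
                 mu_max = mu_max, max_iter = max_iter, tol = tol),
            class = "solver_config")
}

#' Locality-constrained low-rank representation of one view
#'
#' Solves, for a features x samples matrix `X`,
#' \deqn{\min_{Z,E} \|Z\|_* + \lambda \|E\|_{2,1}
#'   \quad s.t. \quad X = XZ + E,\; Z^\top 1 = 1,\; Z_{ij} = 0 \;
#'   \forall (i,j) \notin \Omega,}
#' where \eqn{\Omega} is the K-nearest-neighbour support from
#' [knn_adjacency()].  The affine constraint `Z' 1 = 1` lets samples be
#' represented by affine (not just linear) combinations of their
#' neighbours; the diagonal is excluded from \eqn{\Omega} so that a sample
#' cannot trivially represent itself.
#'
#' The problem is solved by a linearized alternating-direction method with
#' adaptive penalty: per iteration a singular-value thresholding step for
#' the low-rank auxiliary `J` ([svt()]), a column-shrinkage step for the
#' error `E` ([l21_shrink()]), one linearized gradient step for `Z`
#' projected onto the support, then multiplier updates and geometric growth
#' of the penalty.  The linearization constant is
#' `eta = ||X||_2^2 + n + 1` (spectral norm; the `n` is the squared spectral
#' norm of the all-ones row from the affine constraint).
#'
#' Internally the data are rescaled to unit spectral norm with the error
#' weight rescaled in step (`X -> X/s`, `lambda -> lambda * s`), an exactly
#' equivalent problem with the same optimal `Z`.  Without this the affine
#' constraint — the only one without an absorbing auxiliary variable —
#' contracts at rate `1 - n / eta` per iteration, which for
#' high-dimensional views (`||X||_2^2 >> n`) is far too slow.  Residuals
#' and the returned `E` are reported in the original data units.
#'
#' @param view an [omics_view()] or numeric matrix (features x samples).
#'   Standardise features beforehand (see [zscore_view()]) if the view mixes
#'   scales.
#' @param support a `neighbor_support` built on the same samples.
#' @param config a [solver_config()].
#' @return An object of class `lrr_solution`: `Z`, `E`, `J`, multipliers
#'   `Y1`, `Y2`, `Y3`, linearization constant `eta`, per-iteration
#'   `residuals` (columns `reconstruction`, `affine`, `gap`), `converged`,
#'   `iterations` and `sample_ids`.
#' @seealso [affinity_from_representation()] to turn `Z` into an affinity
#'   matrix.
#' @export
solve_lrr <- function(view, support, config = solver_config()) {
  X <- if (inherits(view, "omics_view")) view$values else view
  stopifnot(inherits(support, "neighbor_support"),
            inherits(config, "solver_config"))
  n <- ncol(X)
  if (ncol(support$support) != n) {
    stop("'support' was built on a different number of samples", call. = FALSE)
  }
  Om <- support$support
  mu <- config$mu_init
  tol <- config$tol

  # equivalent rescaling to unit spectral norm (see Details)
  s_norm <- svd(X, nu = 0, nv = 0)$d[1]
  if (s_norm <= 0) s_norm <- 1
  X <- X / s_norm
  lambda <- config$lambda * s_norm

  Z <- matrix(0, n, n); J <- Z; Y3 <- Z
  E <- matrix(0, nrow(X), n); Y1 <- E
  Y2 <- rep(0, n)
  eta <- 1 + n + 1                       # ||X||_2^2 + n + 1 after rescaling
  ones_col <- matrix(1, n, 1)

  res_hist <- matrix(NA_real_, config$max_iter, 3,
                     dimnames = list(NULL, c("reconstruction", "affine", "gap")))
  converged <- FALSE
  k <- 0L
  r <- c(Inf, Inf, Inf)
  while (k < config$max_iter) {
    k <- k + 1L
    # low-rank auxiliary
    J <- svt(Z + Y3 / mu, 1 / mu)
    # sample-sparse error (uses the current Z)
    XZ <- X %*% Z
    E <- l21_shrink(X - XZ + Y1 / mu, lambda / mu)
    # linearized step on Z, projected onto the support
    R1 <- X - XZ - E + Y1 / mu
    r2 <- 1 - colSums(Z) + Y2 / mu
    H <- -crossprod(X, R1) - ones_col %*% r2 + (Z - J + Y3 / mu)
    Z <- Z - H / eta
    Z[!Om] <- 0
    # multipliers and residuals
    C1 <- X - X %*% Z - E
    C2 <- 1 - colSums(Z)
    C3 <- Z - J
    Y1 <- Y1 + mu * C1
    Y2 <- Y2 + mu * C2
    Y3 <- Y3 + mu * C3
    r <- c(s_norm * max_abs(C1), max_abs(C2), max_abs(C3))
    res_hist[k, ] <- r
    if (any(!is.finite(r))) {
      bad <- c("reconstruction", "affine", "gap")[which(!is.finite(r))[1]]
      stop(sprintf("solve_lrr diverged at iteration %d: %s residual is non-finite", k, bad),
           call. = FALSE)
    }
    if (max(r) <= tol) { converged <- TRUE; break }
    mu <- min(config$mu_max, config$mu_growth * mu)
  }
  if (!converged) {
    warning(sprintf("solve_lrr did not converge in %d iterations (max residual %.3g > tol %.3g)",
                    config$max_iter, max(r), tol), call. = FALSE)
  }
  ids <- support$sample_ids
  if (!is.null(ids)) dimnames(Z) <- list(ids, ids)
  E <- s_norm * E                        # back to original data units
  structure(list(Z = Z, E = E, J = J, Y1 = Y1, Y2 = Y2, Y3 = Y3, eta = eta,
                 residuals = res_hist[seq_len(k), , drop = FALSE],
                 converged = converged, iterations = k,
                 sample_ids = ids, config = config),
            class = "lrr_solution")
}

#' @export
print.lrr_solution <- function(x, ...) {
  r <- x$residuals[x$iterations, ]
  cat(sprintf("<lrr_solution> %d samples, %s after %d iterations\n",
              ncol(x$Z),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  final residuals: reconstruction %.2e, affine %.2e, gap %.2e\n",
              r[1], r[2], r[3]))
  invisible(x)
}

#' Sample affinity matrix from a representation solution
#'
#' `W = (|Z| + |Z'|) / 2`: symmetric and nonnegative by construction.
#'
#' @param solution an `lrr_solution` (or a plain coefficient matrix `Z`).
#' @return n x n affinity matrix with sample identifiers as dimnames.
#' @export
affinity_from_representation <- function(solution) {
  Z <- if (inherits(solution, "lrr_solution")) solution$Z else solution
  if (any(!is.finite(Z))) stop("'Z' contains non-finite entries", call. = FALSE)
  (abs(Z) + t(abs(Z))) / 2
}
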
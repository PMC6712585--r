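# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls do not perturb user-level reproducibility.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# max |x|, empty-safe
max_abs <- function(x) if (length(x) == 0) 0 else max(abs(x))

stopifnot_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    stop(sprintf("'%s' must be a single finite%s number", name,
                 if (positive) " positive" else ""), call. = FALSE)
  }
  invisible(x)
}

check_square_symmetric <- function(W, name = "W", tol = 1e-8) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (any(!is.finite(W))) {
    stop(sprintf("'%s' contains non-finite entries", name), call. = FALSE)
  }
  if (max_abs(W - t(W)) > tol * max(1, max_abs(W))) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  if (min(W) < -tol) {
    stop(sprintf("'%s' must be nonnegative", name), call. = FALSE)
  }
  invisible(W)
}

# Pull a plain affinity matrix out of the containers used across modules.
as_affinity_matrix <- function(W) {
  if (inherits(W, "fused_network")) return(W$W)
  if (inherits(W, "lrr_solution")) {
    stop("pass the result of affinity_from_representation(), not the raw solve",
         call. = FALSE)
  }
  W
}

# Orthonormal basis of a random h x d Gaussian matrix.
random_orthonormal <- function(h, d) {
  qr.Q(qr(matrix(rnorm(h * d), h, d)))
}

unit_columns <- function(C) {
  nrm <- sqrt(colSums(C^2))
  nrm[nrm == 0] <- 1
  sweep(C, 2, nrm, `/`)
}
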
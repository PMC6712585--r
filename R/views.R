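#' Construct an omics view
#'
#' An omics view is one data type's measurement matrix over a common sample
#' set: `h` features in rows, `n` samples in columns.  All views passed to a
#' single run must share the same samples; [run_msca()] reconciles sample
#' order by identifier.
#'
#' @param values numeric matrix, features x samples. No missing values.
#' @param sample_ids character vector of `n` unique sample identifiers.
#'   Defaults to `colnames(values)`.
#' @param view_name single string labelling the data type.
#' @return An object of class `omics_view` with elements `values`,
#'   `sample_ids` and `view_name`.
#' @examples
#' X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
#' v <- omics_view(X, view_name = "expression")
#' v
#' @export
omics_view <- function(values, sample_ids = colnames(values),
                       view_name = "view") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing or non-finite value at feature row %d, sample column %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  n <- ncol(values)
  if (n < 3) stop("a view needs at least 3 samples", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) {
    stop("'sample_ids' length must equal the number of columns", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("duplicate sample identifier: '%s'",
                 sample_ids[duplicated(sample_ids)][1]), call. = FALSE)
  }
  colnames(values) <- sample_ids
  structure(list(values = values, sample_ids = sample_ids,
                 view_name = as.character(view_name)[1]),
            class = "omics_view")
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("<omics_view> '%s': %d features x %d samples\n",
              x$view_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a view from a delimited text file
#'
#' Expects a rectangular table whose first row holds sample identifiers and
#' whose first column holds feature identifiers (the conventional
#' features-x-samples orientation of omics matrices).  Use
#' `transposed = TRUE` for samples-in-rows files.
#'
#' @param path path to a TSV/CSV file.
#' @param transposed logical; if `TRUE` the file stores samples in rows.
#' @param sep field separator; tab by default, use `","` for CSV.
#' @param view_name label for the view; defaults to the file name.
#' @return An [omics_view()].
#' @export
read_view <- function(path, transposed = FALSE, sep = "\t",
                      view_name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- read.delim(path, sep = sep, header = TRUE, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("'%s': expected identifiers plus at least one data column", path),
                         call. = FALSE)
  ids <- as.character(df[[1]])
  body <- df[-1]
  M <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, colnames(body)))
  for (j in seq_along(body)) {
    col <- body[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | is.nan(num))
    if (length(bad)) {
      stop(sprintf("'%s': non-numeric or missing cell at row '%s', column '%s' (value '%s')",
                   path, ids[bad[1]], colnames(body)[j], as.character(col[bad[1]])),
           call. = FALSE)
    }
    M[, j] <- num
  }
  if (transposed) M <- t(M)
  omics_view(M, view_name = view_name)
}

#' Write a matrix as TSV with identifier headers
#'
#' @param M matrix with row and column names.
#' @param path output file path.
#' @param id_header name for the identifier column, first header field.
#' @export
write_matrix_tsv <- function(M, path, id_header = "id") {
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster labels as a two-column TSV
#'
#' @param labels named integer vector (names are sample identifiers) or a
#'   [ratio_cut_spectral()] result.
#' @param path output file path.
#' @export
write_labels_tsv <- function(labels, path) {
  if (inherits(labels, "clustering_result")) labels <- labels$labels
  df <- data.frame(sample_id = names(labels), cluster = as.integer(labels),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-feature standardisation of a view
#'
#' Centres each feature (row) and scales it to unit variance, so that views
#' measured on different scales contribute comparably to neighbourhood
#' construction and to the representation penalty.  Constant features are
#' centred and left at zero.
#'
#' @param view an [omics_view()].
#' @return The view with standardised `values`.
#' @export
zscore_view <- function(view) {
  stopifnot(inherits(view, "omics_view"))
  X <- view$values
  mu <- rowMeans(X)
  s <- apply(X, 1, sd)
  s[s == 0 | !is.finite(s)] <- 1
  view$values <- (X - mu) / s
  view
}
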
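# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Symmetry check with a numerical tolerance appropriate for accumulated
## floating-point error in matrix products.
is_symmetric_matrix <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) &&
    max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

assert_square_labelled <- function(M, what = "matrix") {
  if (!is.matrix(M) || !is.numeric(M)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (nrow(M) != ncol(M)) stop(sprintf("%s must be square", what), call. = FALSE)
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stop(sprintf("%s must have row and column labels", what), call. = FALSE)
  }
  if (!identical(rownames(M), colnames(M))) {
    stop(sprintf("%s row and column labels must match", what), call. = FALSE)
  }
  invisible(M)
}

## Lower-triangle (i > j) extraction as a dyad table preserving labels.
lower_triangle_pairs <- function(labels) {
  n <- length(labels)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(
    i = labels[idx[, "row"]],
    j = labels[idx[, "col"]],
    row = idx[, "row"],
    col = idx[, "col"],
    stringsAsFactors = FALSE
  )
}

## Scale a vector by its sample standard deviation (n - 1 denominator),
## without centring. Errors when the column carries no variation.
scale_by_sd <- function(x, name) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("zero-variance column: %s", name), call. = FALSE)
  }
  x / s
}

## Seeds derived from a master seed, kept within the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483647)
}
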
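#' Labelled distance matrices
#'
#' A `dist_matrix` is a square, symmetric, non-negative numeric matrix with a
#' zero diagonal and row/column labels — the common currency for community
#' dissimilarity, geographic distance and environmental difference. The
#' constructor validates symmetry (tolerance 1e-9), the zero diagonal and
#' label consistency.
#'
#' @param x A square numeric matrix with identical row and column names, or
#'   an object coercible to one (e.g. a `dist`).
#' @param labels Optional character vector of labels, used when `x` carries
#'   no dimnames.
#' @return An object of class `dist_matrix` (a base matrix underneath).
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' dist_matrix(m)
#' @export
dist_matrix <- function(x, labels = NULL) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix.")
  if (nrow(x) != ncol(x)) abort("`x` must be square.")
  if (is.null(rownames(x))) {
    labels <- labels %||% paste0("item", seq_len(nrow(x)))
    dimnames(x) <- list(labels, labels)
  }
  if (!identical(rownames(x), colnames(x))) {
    abort("Row and column labels must be identical and in the same order.")
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("Duplicated label: '%s'.", rownames(x)[duplicated(rownames(x))][1]))
  }
  asym <- abs(x - t(x))
  if (any(asym > 1e-9)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Matrix is asymmetric beyond 1e-9: worst cell pair ('%s', '%s') with |%g - %g| = %g.",
      rownames(x)[idx[1]], colnames(x)[idx[2]],
      x[idx[1], idx[2]], x[idx[2], idx[1]], asym[idx[1], idx[2]]
    ))
  }
  x <- (x + t(x)) / 2
  if (any(diag(x) != 0)) {
    bad <- rownames(x)[which(diag(x) != 0)[1]]
    abort(sprintf("Diagonal must be exactly 0; label '%s' has %g.", bad, x[bad, bad]))
  }
  if (any(x < 0)) abort("Distance values must be non-negative.")
  structure(x, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %d labels>\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname dist_matrix
#' @export
is_dist_matrix <- function(x) inherits(x, "dist_matrix")

dm_labels <- function(x) rownames(x)

# Strictly-upper-triangle entries in a fixed (column-major) order.
upper_tri_values <- function(x) {
  x <- unclass(as.matrix(x))
  x[upper.tri(x)]
}

check_same_labels <- function(a, b) {
  if (!identical(dm_labels(a), dm_labels(b))) {
    abort("Distance matrices must share the same labels in the same order.")
  }
}

#' Turn a distance matrix into a long tibble
#'
#' @param x A [dist_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `item_i`, `item_j`, `distance`, one row per
#'   unordered pair (upper triangle).
#' @export
tidy.dist_matrix <- function(x, ...) {
  labs <- dm_labels(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    item_i = labs[idx[, 1]], item_j = labs[idx[, 2]],
    distance = unclass(x)[upper.tri(x)]
  )
}

#' Read and write labelled distance matrices as TSV
#'
#' `write_distance_matrix()` emits the full square matrix with a leading
#' label column; `read_distance_matrix()` reads one back and validates
#' symmetry (tolerance 1e-9, naming the worst cell pair on failure) and the
#' zero diagonal.
#'
#' @param x A [dist_matrix()].
#' @param path File path.
#' @return `read_distance_matrix()` returns a [dist_matrix()];
#'   `write_distance_matrix()` returns `path` invisibly.
#' @export
write_distance_matrix <- function(x, path) {
  stopifnot(is_dist_matrix(x))
  df <- data.frame(label = dm_labels(x), unclass(x), check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  labs <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), labs)) {
    abort("Row labels and column headers do not match.")
  }
  rownames(m) <- labs
  dist_matrix(m)
}
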
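#' Coerce and validate a labeled dissimilarity matrix
#'
#' A dissimilarity here is a complete weighting of the 2-subsets of a label
#' set: a square symmetric numeric matrix with strictly positive off-diagonal
#' entries and unique row/column labels. Every function in this package that
#' consumes a dissimilarity passes it through this validator.
#'
#' Small asymmetries (relative difference up to \code{tol}) are repaired by
#' averaging the upper and lower triangles, since files written with rounded
#' digits are rarely bit-symmetric. Larger asymmetries are an error naming
#' the first offending pair. The diagonal is forced to zero.
#'
#' @param x a square numeric matrix, or a \code{\link[stats]{dist}} object.
#' @param labels optional character vector of vertex labels; defaults to the
#'   dimnames of \code{x}, or \code{"v1"..."vn"} when absent.
#' @param tol relative tolerance for symmetry repair (default \code{1e-9}).
#' @return a symmetric numeric matrix with zero diagonal, positive
#'   off-diagonal entries and label dimnames.
#' @examples
#' as_dissimilarity(matrix(c(0, 1, 1, 0), 2, 2,
#'   dimnames = list(c("a", "b"), c("a", "b"))))
#' @export
as_dissimilarity <- function(x, labels = NULL, tol = 1e-9) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_validation("dissimilarity must be a numeric matrix or 'dist' object")
  n <- nrow(x)
  if (ncol(x) != n)
    stop_format("dissimilarity matrix is not square: ", n, " x ", ncol(x))
  if (n < 2L)
    stop_validation("a dissimilarity needs at least 2 labels, got ", n)
  if (is.null(labels)) {
    labels <- rownames(x)
    if (is.null(labels)) labels <- colnames(x)
    if (is.null(labels)) labels <- paste0("v", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n)
    stop_validation("expected ", n, " labels, got ", length(labels))
  if (anyDuplicated(labels))
    stop_validation("duplicate labels: ",
      paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (anyNA(x))
    stop_validation("dissimilarity matrix contains missing values")

  diff <- abs(x - t(x))
  scale <- pmax(abs(x), abs(t(x)), 1e-300)
  bad <- which(diff > tol * scale, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop_format("matrix not symmetric at (", labels[i], ", ", labels[j],
      "): ", x[i, j], " vs ", x[j, i])
  }
  x <- (x + t(x)) / 2
  diag(x) <- 0
  off <- x[upper.tri(x)]
  if (any(off <= 0)) {
    bad <- which(x <= 0 & upper.tri(x), arr.ind = TRUE)
    stop_validation("off-diagonal dissimilarities must be strictly positive; ",
      "W(", labels[bad[1L, 1L]], ", ", labels[bad[1L, 2L]], ") = ",
      x[bad[1L, 1L], bad[1L, 2L]])
  }
  dimnames(x) <- list(labels, labels)
  x
}
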
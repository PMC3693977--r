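#' @export
print.ultranet <- function(x, ...) {
  cat("Ultrametric network (", x$n, " vertices)\n", sep = "")
  exact_n <- sum(x$edges$exact)
  cat("  exact edges: ", exact_n, sep = "")
  if (x$delta > 0)
    cat("  (+", nrow(x$edges) - exact_n, " within delta = ",
      format(x$delta), ")", sep = "")
  cat("\n")
  if (length(x$artificial))
    cat("  artificial vertices: ", length(x$artificial), " (",
      paste(x$artificial, collapse = ", "), ")\n", sep = "")
  cat("  elementary steps: ", x$steps, "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted ultrametric network
#'
#' @param object an \code{"ultranet"} fit.
#' @param ... unused.
#' @return a list of class \code{"summary.ultranet"} with vertex/edge
#'   counts, the relaxation and augmentation parameters, the range of
#'   subdominant ultrametric values, and the total weight of the rendered
#'   graph.
#' @export
summary.ultranet <- function(object, ...) {
  ut <- upper.tri(object$W)
  structure(list(
    n = object$n,
    n_edges = nrow(object$edges),
    n_exact = sum(object$edges$exact),
    n_possible = sum(ut),
    delta = object$delta,
    augment_threshold = object$augment_threshold,
    n_artificial = length(object$artificial),
    wstar_range = range(object$Wstar[ut]),
    max_deviation = max(object$W[ut] - object$Wstar[ut]),
    graph_weight = sum(object$graph$weight),
    steps = object$steps
  ), class = "summary.ultranet")
}

#' @export
print.summary.ultranet <- function(x, ...) {
  cat("Ultrametric network summary\n")
  cat("  vertices:          ", x$n, "\n", sep = "")
  cat("  edges:             ", x$n_edges, " of ", x$n_possible,
    " pairs (", x$n_exact, " exact)\n", sep = "")
  cat("  delta:             ", format(x$delta), "\n", sep = "")
  if (!is.null(x$augment_threshold))
    cat("  artificial vertices:", x$n_artificial, " (threshold ",
      format(x$augment_threshold), ")\n", sep = "")
  cat("  W* range:          [", format(x$wstar_range[1]), ", ",
    format(x$wstar_range[2]), "]\n", sep = "")
  cat("  max W - W*:        ", format(x$max_deviation), "\n", sep = "")
  cat("  total graph weight:", format(x$graph_weight), "\n")
  invisible(x)
}

#' @export
as.matrix.ultranet <- function(x, which = c("wstar", "input"), ...) {
  which <- match.arg(which)
  if (which == "wstar") x$Wstar else x$W
}

#' Plot a fitted ultrametric network
#'
#' Draws the final graph (after relaxation and augmentation) with igraph.
#' Artificial median vertices are shown as small squares; delta-relaxed
#' edges are dashed. Edge labels show the dissimilarity.
#'
#' @param x an \code{"ultranet"} fit.
#' @param edge_labels logical: print edge weights (default TRUE for graphs
#'   with at most 40 edges).
#' @param ... passed on to \code{\link[igraph]{plot.igraph}}.
#' @export
plot.ultranet <- function(x, edge_labels = NULL, ...) {
  g <- as_igraph_network(x)
  art <- igraph::V(g)$artificial
  if (is.null(edge_labels)) edge_labels <- igraph::ecount(g) <= 40L
  igraph::plot.igraph(g,
    vertex.shape = ifelse(art, "square", "circle"),
    vertex.size = ifelse(art, 6, 14),
    vertex.color = ifelse(art, "grey40", "lightsteelblue"),
    edge.lty = ifelse(igraph::E(g)$exact, 1, 2),
    edge.label = if (edge_labels) format(igraph::E(g)$weight, digits = 3),
    ...)
  invisible(x)
}
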
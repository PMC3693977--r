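#' Delta-relaxed ultrametric network
#'
#' Recomputes the edge set of a fitted network under a new relaxation
#' tolerance: a pair {u, v} is an edge of the delta-network whenever
#' W(u,v) <= W*(u,v) + delta. The subdominant ultrametric is not recomputed
#' -- relaxation is a postprocess on the stored W and W*, and runs in O(n^2).
#'
#' With delta = 0 the condition reduces to equality and the exact network is
#' returned; the edge set grows monotonically with delta, and once delta
#' reaches the largest dissimilarity the network is complete. On its member
#' pairs the relaxed graph's weight map coincides with min(W, W* + delta),
#' i.e. each admitted edge keeps its observed dissimilarity as weight. Both
#' W and W* are kept per edge so renderers can display the deviation.
#'
#' @param object an \code{"ultranet"} fit.
#' @param delta nonnegative tolerance, in the units of the input
#'   dissimilarity.
#' @return a new \code{"ultranet"} fit with the relaxed edge set (and, if the
#'   original fit requested augmentation, augmentation re-applied to the
#'   relaxed network).
#' @examples
#' fit <- ultranet(canonical4())
#' nrow(delta_network(fit, 2)$edges)  # 4: edge a-c enters (W=4 <= 2+2)
#' @export
delta_network <- function(object, delta) {
  stopifnot(inherits(object, "ultranet"))
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop_validation("delta must be a single nonnegative number")
  object$delta <- delta
  assemble_network(object)
}
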
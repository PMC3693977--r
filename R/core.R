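#' Fit an ultrametric network to a dissimilarity
#'
#' Computes, in a single O(n^2) pass, the subdominant ultrametric W* of a
#' dissimilarity W -- the unique largest ultrametric with W*(u,v) <= W(u,v)
#' everywhere -- together with the ultrametric network: the graph on the same
#' vertices whose edges are exactly the pairs with W(u,v) = W*(u,v). That
#' edge set equals the union of the edge sets of all minimum spanning trees
#' of the weighted complete graph, so the network generalizes the single
#' minimum spanning tree that distance-based phylogenetics traditionally
#' draws, keeping every tied alternative connection.
#'
#' The algorithm grows a settled vertex set Prim-style from a deterministic
#' seed (the first label; the result is seed-independent). At each step the
#' pending vertex \code{u} with the cheapest connection \code{key[u]} to the
#' settled set is annexed through its parent \code{p}, and the ultrametric
#' estimates are extended by \code{d(u,p) = key[u]} and
#' \code{d(u,v) = max(key[u], d(p,v))} for every other settled \code{v};
#' settled pairs are never revisited, which is where the factor-n saving over
#' the Floyd-Warshall closure comes from. Ties in the key are broken by label
#' order; W* and the edge set are provably tie-invariant, so the choice has
#' no observable effect. An elementary-step counter is carried along so the
#' quadratic growth can be verified empirically (see \code{$steps}).
#'
#' Two optional post-processing stages, applied in this order:
#' \describe{
#'   \item{delta-relaxation}{edges are admitted whenever
#'     \code{W(u,v) <= W*(u,v) + delta}, adding near-optimal connections;
#'     \code{delta = 0} gives the exact network.}
#'   \item{augmentation}{heavy triangles (perimeter strictly above
#'     \code{augment_threshold}) are replaced by a three-edge star through an
#'     artificial median vertex; see [insert_artificial_vertices()].}
#' }
#'
#' @param D a dissimilarity: square symmetric positive matrix,
#'   \code{\link[stats]{dist}} object, or anything [as_dissimilarity()]
#'   accepts.
#' @param delta nonnegative relaxation tolerance, in the units of \code{D}
#'   (default 0: exact network).
#' @param augment_threshold if non-\code{NULL}, insert artificial median
#'   vertices into triangles whose perimeter exceeds this value.
#' @param labels optional vertex labels overriding the dimnames of \code{D}.
#' @return an object of class \code{"ultranet"}: a list with components
#'   \item{labels}{vertex labels, in input order.}
#'   \item{W}{the validated input dissimilarity matrix.}
#'   \item{Wstar}{the subdominant ultrametric matrix.}
#'   \item{edges}{data.frame of network edges (\code{u}, \code{v},
#'     \code{weight} = W, \code{wstar}, logical \code{exact}); the
#'     delta-relaxed network when \code{delta > 0}.}
#'   \item{graph}{data.frame of the edges of the final rendered graph --
#'     equal to \code{edges} unless augmentation ran, in which case replaced
#'     triangles are rewired through artificial vertices.}
#'   \item{artificial}{labels ("N1", "N2", ...) of inserted median vertices.}
#'   \item{provenance}{for each artificial vertex, the triangle it replaced.}
#'   \item{delta, augment_threshold}{the parameters used.}
#'   \item{steps}{instrumented count of elementary operations (Theta(n^2)).}
#' @examples
#' fit <- ultranet(canonical4())
#' fit$edges            # the path a-b, b-c, c-d
#' as.matrix(fit)       # W*
#' ultranet(canonical4(), delta = 2)$edges  # gains the edge a-c
#' @seealso [bottleneck_closure()] and [all_mst_edge_union()] for
#'   brute-force cross-checks; [delta_network()] to re-relax a fit;
#'   [write_network()] to export.
#' @export
ultranet <- function(D, delta = 0, augment_threshold = NULL, labels = NULL) {
  W <- as_dissimilarity(D, labels = labels)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop_validation("delta must be a single nonnegative number")
  if (!is.null(augment_threshold) &&
      (!is.numeric(augment_threshold) || length(augment_threshold) != 1L ||
       is.na(augment_threshold) || augment_threshold < 0))
    stop_validation("augment_threshold must be NULL or a single nonnegative number")

  core <- ultranet_prim(W)
  fit <- structure(
    list(labels = rownames(W), W = W, Wstar = core$Wstar, edges = NULL,
         graph = NULL, artificial = character(0), provenance = list(),
         skipped_triangles = NULL, delta = delta,
         augment_threshold = augment_threshold, steps = core$steps,
         n = nrow(W), call = match.call()),
    class = "ultranet")
  assemble_network(fit)
}

# The Prim-style incremental closure. Returns W* and the elementary-step
# counter. d(u, v) for a newly annexed u is max(key[u], d(parent, v)):
# the path u -> parent realizes key[u] and parent -> v realizes d(parent, v),
# and no cheaper bottleneck can exist because key[u] is the cheapest crossing
# of the cut separating u from the settled set.
ultranet_prim <- function(W) {
  n <- nrow(W)
  lab <- rownames(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  r <- 1L  # deterministic seed: first label
  key <- W[r, ]
  prec <- rep.int(r, n)
  key[r] <- NA_real_
  settled <- integer(n)
  settled[1L] <- r
  ns <- 1L
  pending <- seq_len(n)[-r]
  steps <- n - 1L  # queue initialization

  while (length(pending) > 0L) {
    kp <- key[pending]
    kmin <- min(kp)
    cand <- pending[kp == kmin]
    u <- if (length(cand) == 1L) cand
      else cand[order(lab[cand], method = "radix")[1L]]
    steps <- steps + length(pending)  # linear scan of the queue

    p <- prec[u]
    kap <- key[u]
    d[u, p] <- kap
    d[p, u] <- kap
    if (ns > 1L) {
      others <- settled[seq_len(ns)]
      others <- others[others != p]
      val <- pmax(kap, d[p, others])
      d[u, others] <- val
      d[others, u] <- val
      steps <- steps + length(others)
    }
    ns <- ns + 1L
    settled[ns] <- u
    pending <- pending[pending != u]

    if (length(pending) > 0L) {
      wu <- W[u, pending]
      upd <- wu < key[pending]
      if (any(upd)) {
        key[pending[upd]] <- wu[upd]
        prec[pending[upd]] <- u
      }
      steps <- steps + length(pending)
    }
  }
  dimnames(d) <- dimnames(W)
  list(Wstar = d, steps = steps)
}

# Build $edges (delta-network) and $graph (post-augmentation) from W, Wstar
# and the fit's parameters. Membership uses a 1e-12 relative tolerance so
# float round-off never drops a mathematically exact edge; maxima of exactly
# representable inputs are themselves exact, so integer weights compare
# exactly.
assemble_network <- function(fit) {
  W <- fit$W
  Ws <- fit$Wstar
  ut <- upper.tri(W)
  slack <- W - Ws  # >= 0 up to round-off, by domination
  tol <- 1e-12 * pmax(abs(W), abs(Ws))
  member <- ut & (slack <= fit$delta + tol)
  exact <- ut & (slack <= tol)
  idx <- which(member, arr.ind = TRUE)
  lab <- fit$labels
  ef <- data.frame(u = lab[idx[, 1L]], v = lab[idx[, 2L]],
    weight = W[idx], wstar = Ws[idx], exact = exact[idx],
    stringsAsFactors = FALSE)
  lv <- sort(lab, method = "radix")
  swap <- match(ef$u, lv) > match(ef$v, lv)
  if (any(swap)) {
    tmp <- ef$u[swap]; ef$u[swap] <- ef$v[swap]; ef$v[swap] <- tmp
  }
  ef <- ef[order(match(ef$u, lv), match(ef$v, lv), method = "radix"), ,
    drop = FALSE]
  row.names(ef) <- NULL
  fit$edges <- ef

  if (is.null(fit$augment_threshold)) {
    fit$graph <- ef[c("u", "v", "weight")]
    fit$artificial <- character(0)
    fit$provenance <- list()
    fit$skipped_triangles <- list()
  } else {
    aug <- insert_artificial_vertices(ef[c("u", "v", "weight")],
      fit$augment_threshold)
    fit$graph <- aug$edges
    fit$artificial <- aug$artificial
    fit$provenance <- aug$provenance
    fit$skipped_triangles <- aug$skipped
  }
  fit
}

#' Subdominant ultrametric value of a single pair
#'
#' Looks up W*(u, v) in a fitted network. The value is the least-resistance
#' bottleneck between the two vertices: the minimum, over all paths
#' connecting them in the complete graph, of the largest dissimilarity
#' crossed along the path.
#'
#' @param object an \code{"ultranet"} fit.
#' @param u,v vertex labels.
#' @return a single number; 0 when \code{u == v}.
#' @examples
#' bottleneck(ultranet(canonical4()), "a", "d")  # 3
#' @export
bottleneck <- function(object, u, v) {
  stopifnot(inherits(object, "ultranet"))
  iu <- match(u, object$labels)
  iv <- match(v, object$labels)
  if (is.na(iu)) stop_lookup("unknown label: ", u)
  if (is.na(iv)) stop_lookup("unknown label: ", v)
  object$Wstar[iu, iv]
}
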
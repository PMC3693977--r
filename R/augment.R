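# Artificial-vertex augmentation: replace heavy triangles by a median
# (Steiner) star. In phylogenetic use the artificial vertex models a missing
# or ancestral haplotype sitting between three observed ones.
#
# All label ordering below is byte-wise (C collation, via radix sorting), so
# canonical orders and output files do not depend on the session locale.

#' Candidate triangles for median-vertex insertion
#'
#' Finds every vertex triple whose three pairwise edges are all present in
#' the network and whose perimeter (sum of the three edge weights) strictly
#' exceeds the threshold. Candidates are returned in the canonical processing
#' order: perimeter descending, ties by the byte-lexicographically sorted
#' label triple, which makes the augmentation independent of edge input
#' order.
#'
#' @param network an \code{"ultranet"} fit, or a data.frame of edges with
#'   columns \code{u}, \code{v}, \code{weight}.
#' @param threshold nonnegative perimeter threshold; only triangles with
#'   perimeter strictly greater are candidates.
#' @return a data.frame with columns \code{a}, \code{b}, \code{c} (sorted
#'   labels) and \code{perimeter}, ordered canonically; zero rows when the
#'   network has no qualifying triangle (any tree, in particular).
#' @export
find_candidate_triangles <- function(network, threshold) {
  ed <- net_edges(network)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop_validation("threshold must be a single nonnegative number")
  adj <- adjacency_of(ed)
  empty <- data.frame(a = character(0), b = character(0), c = character(0),
    perimeter = numeric(0), stringsAsFactors = FALSE)
  n <- length(adj$labels)
  if (n < 3L) return(empty)
  A <- adj$A
  tri_a <- integer(0); tri_b <- integer(0); tri_c <- integer(0)
  per <- numeric(0)
  for (i in seq_len(n - 2L)) {
    js <- which(!is.na(A[i, ]))
    js <- js[js > i]
    for (j in js) {
      ks <- js[js > j & !is.na(A[j, ][js])]
      if (length(ks) == 0L) next
      p <- A[i, j] + A[i, ks] + A[j, ks]
      keep <- p > threshold
      if (any(keep)) {
        tri_a <- c(tri_a, rep.int(i, sum(keep)))
        tri_b <- c(tri_b, rep.int(j, sum(keep)))
        tri_c <- c(tri_c, ks[keep])
        per <- c(per, p[keep])
      }
    }
  }
  if (length(per) == 0L) return(empty)
  ord <- order(-per, tri_a, tri_b, tri_c, method = "radix")
  data.frame(a = adj$labels[tri_a[ord]], b = adj$labels[tri_b[ord]],
    c = adj$labels[tri_c[ord]], perimeter = per[ord],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Median (Steiner point) distances for a triangle
#'
#' Given the three pairwise distances of a triangle on vertices u, w, y,
#' returns the distances from the median point x to each corner: the unique
#' solution of the path equations d(x,u) + d(x,w) = d(u,w) (and cyclically),
#' i.e. the Gromov products
#' \deqn{d(x,u) = (d(u,w) + d(u,y) - d(w,y)) / 2}
#' and cyclic permutations. The three-edge star through x realizes each
#' original pairwise distance exactly while weighing only half the triangle
#' perimeter.
#'
#' A degenerate triangle (triangle inequality tight or violated) yields a
#' zero or negative edge; callers treat that as "do not insert".
#'
#' @param d_uw,d_uy,d_wy the three pairwise distances, positive.
#' @return a named numeric vector \code{c(xu, xw, xy)} of corner distances.
#' @examples
#' median_distances(4, 6, 8)  # c(xu = 1, xw = 3, xy = 5)
#' @export
median_distances <- function(d_uw, d_uy, d_wy) {
  if (!all(is.finite(c(d_uw, d_uy, d_wy))) || any(c(d_uw, d_uy, d_wy) <= 0))
    stop_validation("triangle distances must be finite and positive")
  c(xu = (d_uw + d_uy - d_wy) / 2,
    xw = (d_uw + d_wy - d_uy) / 2,
    xy = (d_uy + d_wy - d_uw) / 2)
}

#' Insert artificial median vertices into heavy triangles
#'
#' Processes the candidate triangles of [find_candidate_triangles()] in
#' canonical order. Each triangle whose three edges are all still present is
#' replaced: its edges are removed and a new vertex ("N1", "N2", ... in
#' creation order) is connected to the three corners at the median distances,
#' so the corner-to-corner path distances through the new vertex equal the
#' removed direct distances exactly, at half the removed weight. A triangle
#' that lost an edge to an earlier insertion is skipped, as is a degenerate
#' triangle whose median star would contain a zero-length edge (with a
#' warning); artificial vertices never seed new candidates (single pass).
#'
#' @param network an \code{"ultranet"} fit, or a data.frame of edges with
#'   columns \code{u}, \code{v}, \code{weight}.
#' @param threshold perimeter threshold, strict (see
#'   [find_candidate_triangles()]).
#' @return a list with components \code{edges} (the augmented edge
#'   data.frame), \code{artificial} (new vertex labels), \code{provenance}
#'   (named list mapping each artificial vertex to its replaced triangle's
#'   corner labels) and \code{skipped} (triangles passed over, with reason
#'   \code{"edge-consumed"} or \code{"degenerate"}).
#' @examples
#' tri <- data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"), weight = 1)
#' aug <- insert_artificial_vertices(tri, threshold = 0)
#' aug$edges   # three edges of weight 0.5 through N1
#' @export
insert_artificial_vertices <- function(network, threshold) {
  ed <- net_edges(network)
  cand <- find_candidate_triangles(ed, threshold)
  adj <- adjacency_of(ed)
  A <- adj$A
  labels <- adj$labels
  artificial <- character(0)
  provenance <- list()
  skipped <- list()
  new_u <- character(0); new_v <- character(0); new_w <- numeric(0)

  for (i in seq_len(nrow(cand))) {
    ia <- match(cand$a[i], labels)
    ib <- match(cand$b[i], labels)
    ic <- match(cand$c[i], labels)
    if (is.na(A[ia, ib]) || is.na(A[ia, ic]) || is.na(A[ib, ic])) {
      skipped[[length(skipped) + 1L]] <-
        list(triangle = c(cand$a[i], cand$b[i], cand$c[i]),
          reason = "edge-consumed")
      next
    }
    med <- median_distances(A[ia, ib], A[ia, ic], A[ib, ic])
    if (any(med <= 0)) {
      warning("skipping degenerate triangle (", cand$a[i], ", ", cand$b[i],
        ", ", cand$c[i], "): median star would contain a zero-length edge",
        call. = FALSE)
      skipped[[length(skipped) + 1L]] <-
        list(triangle = c(cand$a[i], cand$b[i], cand$c[i]),
          reason = "degenerate")
      next
    }
    x <- paste0("N", length(artificial) + 1L)
    artificial <- c(artificial, x)
    provenance[[x]] <- c(cand$a[i], cand$b[i], cand$c[i])
    A[ia, ib] <- A[ib, ia] <- NA_real_
    A[ia, ic] <- A[ic, ia] <- NA_real_
    A[ib, ic] <- A[ic, ib] <- NA_real_
    new_u <- c(new_u, cand$a[i], cand$b[i], cand$c[i])
    new_v <- c(new_v, x, x, x)
    new_w <- c(new_w, as.numeric(med))
  }

  keep <- which(!is.na(A) & upper.tri(A), arr.ind = TRUE)
  out <- edge_frame(c(labels[keep[, 1L]], new_u),
                    c(labels[keep[, 2L]], new_v),
                    c(A[keep], new_w))
  list(edges = out, artificial = artificial, provenance = provenance,
    skipped = skipped)
}

# --- internal helpers -------------------------------------------------------

# weight matrix (NA = absent edge) over the radix-sorted label set
adjacency_of <- function(ed) {
  labels <- sort(unique(c(ed$u, ed$v)), method = "radix")
  n <- length(labels)
  A <- matrix(NA_real_, n, n)
  iu <- match(ed$u, labels)
  iv <- match(ed$v, labels)
  A[cbind(iu, iv)] <- ed$weight
  A[cbind(iv, iu)] <- ed$weight
  list(labels = labels, A = A)
}

# canonical pair keys under byte ordering; consistent with edge_frame()
ekey <- function(u, v) {
  lv <- sort(unique(c(u, v)), method = "radix")
  iu <- match(u, lv)
  iv <- match(v, lv)
  s <- iu > iv
  paste(ifelse(s, v, u), ifelse(s, u, v), sep = "\t")
}

net_edges <- function(network) {
  if (inherits(network, "ultranet")) {
    ed <- network$edges[c("u", "v", "weight")]
  } else if (is.data.frame(network)) {
    if (!all(c("u", "v", "weight") %in% names(network)))
      stop_validation("edge data.frame needs columns u, v, weight")
    ed <- network[c("u", "v", "weight")]
    ed$u <- as.character(ed$u)
    ed$v <- as.character(ed$v)
  } else {
    stop_validation("network must be an 'ultranet' fit or an edge data.frame")
  }
  if (nrow(ed) == 0L) stop_validation("network has no edges")
  if (any(ed$u == ed$v)) stop_validation("self-loops are not allowed")
  if (anyDuplicated(ekey(ed$u, ed$v)))
    stop_validation("duplicate edges in network")
  row.names(ed) <- NULL
  ed
}
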
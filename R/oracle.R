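# Brute-force reference implementations. These are deliberately naive and
# size-capped: they exist so that the O(n^2) algorithm in ultranet() can be
# cross-validated on small instances, by users as well as by the test suite.

#' Subdominant ultrametric by Floyd-Warshall bottleneck closure
#'
#' Reference O(n^3) computation of the subdominant ultrametric: starting from
#' the dissimilarity itself, each vertex in turn is used as a pivot and every
#' pair is relaxed through it with the minimax rule
#' \code{M(u,v) <- min(M(u,v), max(M(u,w), M(w,v)))}. After all pivots,
#' \code{M(u,v)} is the minimum over all paths from u to v of the largest
#' edge weight on the path -- the bottleneck distance, which equals the
#' largest ultrametric dominated by the input.
#'
#' @param D a dissimilarity accepted by [as_dissimilarity()].
#' @return a symmetric matrix: the subdominant ultrametric, with labels.
#' @seealso [ultranet()] for the O(n^2) computation this validates.
#' @examples
#' W <- canonical4()
#' bottleneck_closure(W)
#' @export
bottleneck_closure <- function(D) {
  M <- as_dissimilarity(D)
  n <- nrow(M)
  for (w in seq_len(n)) {
    through <- pmax(matrix(M[, w], n, n), matrix(M[w, ], n, n, byrow = TRUE))
    M <- pmin(M, through)
  }
  diag(M) <- 0
  M
}

#' Union of the edge sets of all minimum spanning trees
#'
#' Enumerates every one of the n^(n-2) spanning trees of the complete graph
#' (via Pruefer sequences, decoded in bulk), finds the minimum total weight,
#' and returns the union of the edge sets of all trees attaining it. This is
#' the defining characterization of the ultrametric network, so the function
#' serves as an exhaustive oracle for small n.
#'
#' @param D a dissimilarity accepted by [as_dissimilarity()].
#' @param max_n refuse instances larger than this (default 9; the tree count
#'   grows as n^(n-2)).
#' @return a data.frame with character columns \code{u}, \code{v} (labels,
#'   \code{u < v} within a row) and numeric \code{weight}, sorted
#'   lexicographically.
#' @examples
#' tri <- as_dissimilarity(matrix(1, 3, 3) - diag(3),
#'   labels = c("a", "b", "c"))
#' all_mst_edge_union(tri)  # all 3 edges: the MSTs are tied
#' @export
all_mst_edge_union <- function(D, max_n = 9L) {
  W <- as_dissimilarity(D)
  n <- nrow(W)
  labels <- rownames(W)
  if (n > max_n)
    stop_capability("exhaustive spanning-tree enumeration capped at n = ",
      max_n, ", got n = ", n)
  if (n == 2L)
    return(edge_frame(labels[1L], labels[2L], W[1L, 2L]))

  m <- n - 2L
  P <- as.matrix(expand.grid(rep(list(seq_len(n)), m), KEEP.OUT.ATTRS = FALSE))
  storage.mode(P) <- "integer"
  nt <- nrow(P)
  deg <- matrix(1L, nt, n)
  for (v in seq_len(n)) deg[, v] <- 1L + as.integer(rowSums(P == v))
  rows <- seq_len(nt)
  eu <- matrix(0L, nt, n - 1L)
  ev <- matrix(0L, nt, n - 1L)
  total <- numeric(nt)
  for (k in seq_len(m)) {
    leaf <- max.col(deg == 1L, ties.method = "first")
    par <- P[, k]
    eu[, k] <- leaf
    ev[, k] <- par
    total <- total + W[cbind(leaf, par)]
    deg[cbind(rows, leaf)] <- 0L
    deg[cbind(rows, par)] <- deg[cbind(rows, par)] - 1L
  }
  isleaf <- deg == 1L
  u1 <- max.col(isleaf, ties.method = "first")
  u2 <- max.col(isleaf, ties.method = "last")
  eu[, n - 1L] <- u1
  ev[, n - 1L] <- u2
  total <- total + W[cbind(u1, u2)]

  best <- min(total)
  win <- which(total <= best * (1 + 1e-12))
  a <- pmin(eu[win, , drop = FALSE], ev[win, , drop = FALSE])
  b <- pmax(eu[win, , drop = FALSE], ev[win, , drop = FALSE])
  keep <- !duplicated(cbind(as.vector(a), as.vector(b)))
  ia <- as.vector(a)[keep]
  ib <- as.vector(b)[keep]
  edge_frame(labels[ia], labels[ib], W[cbind(ia, ib)])
}

#' Minimum-bottleneck value by exhaustive simple-path enumeration
#'
#' Third, independent route to the subdominant ultrametric value of a single
#' pair: enumerate every simple path between the two vertices and take the
#' minimum, over paths, of the maximum edge weight along the path
#' (the path's bottleneck). Exponential; capped at small n.
#'
#' @param D a dissimilarity accepted by [as_dissimilarity()].
#' @param u,v two distinct vertex labels.
#' @param max_n refuse instances larger than this (default 8).
#' @return the minimax path value, a single number.
#' @examples
#' min_bottleneck_by_paths(canonical4(), "a", "d")  # 3, via a-b-c-d
#' @export
min_bottleneck_by_paths <- function(D, u, v, max_n = 8L) {
  W <- as_dissimilarity(D)
  n <- nrow(W)
  labels <- rownames(W)
  if (n > max_n)
    stop_capability("simple-path enumeration capped at n = ", max_n,
      ", got n = ", n)
  iu <- match(u, labels)
  iv <- match(v, labels)
  if (is.na(iu)) stop_lookup("unknown label: ", u)
  if (is.na(iv)) stop_lookup("unknown label: ", v)
  if (iu == iv) return(0)

  best <- Inf
  visited <- logical(n)
  recurse <- function(at, cur) {
    if (cur >= best) return(invisible(NULL))  # prune: can't improve
    if (at == iv) {
      best <<- cur
      return(invisible(NULL))
    }
    visited[at] <<- TRUE
    for (nxt in seq_len(n)) {
      if (!visited[nxt]) recurse(nxt, max(cur, W[at, nxt]))
    }
    visited[at] <<- FALSE
    invisible(NULL)
  }
  recurse(iu, 0)
  best
}

# Canonical sorted edge list used by oracles and network accessors.
# Ordering is byte-wise (radix), independent of the session locale.
edge_frame <- function(u, v, weight) {
  lv <- sort(unique(c(u, v)), method = "radix")
  iu <- match(u, lv)
  iv <- match(v, lv)
  swap <- iu > iv
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  ord <- order(match(u, lv), match(v, lv), method = "radix")
  data.frame(u = u[ord], v = v[ord], weight = weight[ord],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' The four-point worked example
#'
#' A small labeled dissimilarity on \{a, b, c, d\} used throughout the
#' documentation and tests: W(a,b)=1, W(b,c)=2, W(c,d)=3, W(a,c)=4,
#' W(a,d)=5, W(b,d)=6. Its ultrametric network is the path a-b-c-d
#' (the unique minimum spanning tree).
#'
#' @return a 4x4 labeled dissimilarity matrix.
#' @export
canonical4 <- function() {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["b", "a"] <- 1
  W["b", "c"] <- W["c", "b"] <- 2
  W["c", "d"] <- W["d", "c"] <- 3
  W["a", "c"] <- W["c", "a"] <- 4
  W["a", "d"] <- W["d", "a"] <- 5
  W["b", "d"] <- W["d", "b"] <- 6
  W
}
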
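# Shared fixture builders: random dissimilarities (continuous or
# small-integer-valued to force MST ties) and axiom checkers.

random_dissim <- function(n, seed, integer = FALSE, max_int = 6L) {
  set.seed(seed)
  k <- n * (n - 1L) / 2L
  vals <- if (integer) as.numeric(sample.int(max_int, k, replace = TRUE))
    else stats::runif(k, 0.1, 10)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  labs <- sprintf("t%02d", seq_len(n))
  dimnames(m) <- list(labs, labs)
  m
}

# strong triangle inequality, checked over all triples
is_ultrametric <- function(M, tol = 1e-9) {
  n <- nrow(M)
  for (w in seq_len(n)) {
    through <- pmax(matrix(M[, w], n, n), matrix(M[w, ], n, n, byrow = TRUE))
    if (any(M > through + tol * pmax(abs(through), 1))) return(FALSE)
  }
  TRUE
}

# byte-ordered pair keys, matching the package's canonical edge ordering
edge_keys <- function(ed) {
  lv <- sort(unique(c(ed$u, ed$v)), method = "radix")
  s <- match(ed$u, lv) > match(ed$v, lv)
  paste(ifelse(s, ed$v, ed$u), ifelse(s, ed$u, ed$v), sep = "|")
}

# minimax (bottleneck) closure over an explicit, possibly incomplete, graph:
# non-edges enter as Inf. Used to check that paths restricted to a single
# MST already realize every subdominant ultrametric value.
closure_of_graph <- function(labels, edges) {
  n <- length(labels)
  M <- matrix(Inf, n, n, dimnames = list(labels, labels))
  diag(M) <- 0
  for (i in seq_len(nrow(edges)))
    M[edges$u[i], edges$v[i]] <- M[edges$v[i], edges$u[i]] <- edges$weight[i]
  for (w in seq_len(n)) {
    through <- pmax(matrix(M[, w], n, n), matrix(M[w, ], n, n, byrow = TRUE))
    M <- pmin(M, through)
  }
  M
}
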
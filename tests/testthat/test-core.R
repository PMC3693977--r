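test_that("the 4-point worked example gives the known W* and network", {
  fit <- ultranet(canonical4())
  Ws <- fit$Wstar
  expect_identical(Ws["a", "b"], 1)
  expect_identical(Ws["b", "c"], 2)
  expect_identical(Ws["a", "c"], 2)
  expect_identical(Ws["c", "d"], 3)
  expect_identical(Ws["a", "d"], 3)
  expect_identical(Ws["b", "d"], 3)
  expect_identical(edge_keys(fit$edges), c("a|b", "b|c", "c|d"))
  expect_true(all(fit$edges$exact))
})

test_that("tied weights yield the union of all tied spanning trees", {
  tri <- as_dissimilarity(matrix(1, 3, 3) - diag(3), labels = c("a", "b", "c"))
  fit <- ultranet(tri)
  expect_identical(edge_keys(fit$edges), c("a|b", "a|c", "b|c"))
  expect_true(all(fit$Wstar[upper.tri(fit$Wstar)] == 1))
})

test_that("two vertices give the single possible edge", {
  W <- as_dissimilarity(matrix(c(0, 7, 7, 0), 2, 2), labels = c("a", "b"))
  fit <- ultranet(W)
  expect_identical(fit$Wstar["a", "b"], 7)
  expect_identical(edge_keys(fit$edges), "a|b")
  expect_error(ultranet(matrix(0, 1, 1)), class = "ultranet_validation_error")
})

test_that("W* matches the closure oracle on random instances, exactly for integers", {
  for (seed in 1:30) {
    n <- sample(3:15, 1)
    W <- random_dissim(n, seed, integer = seed %% 2 == 0)
    fit <- ultranet(W)
    ref <- bottleneck_closure(W)
    if (seed %% 2 == 0) expect_identical(fit$Wstar, ref)
    else expect_equal(fit$Wstar, ref, tolerance = 1e-12)
  }
})

test_that("W* satisfies the ultrametric axioms and dominates nothing above W", {
  for (seed in 1:10) {
    W <- random_dissim(8, seed, integer = seed %% 2 == 0)
    Ws <- ultranet(W)$Wstar
    expect_true(is_ultrametric(Ws, tol = 1e-12))
    expect_true(all(Ws <= W + 1e-12 * abs(W)))
  }
})

test_that("W* is maximal: any upward perturbation breaks an axiom", {
  for (seed in 1:8) {
    W <- random_dissim(6, seed)
    Ws <- ultranet(W)$Wstar
    labs <- rownames(W)
    for (pick in 1:4) {
      ij <- sample(6, 2)
      i <- ij[1]; j <- ij[2]
      for (eps in c(1e-9, 0.01, 1)) {
        P <- Ws
        P[i, j] <- P[j, i] <- P[i, j] + eps
        broke <- !is_ultrametric(P, tol = 0) || P[i, j] > W[i, j]
        expect_true(broke, info = sprintf("seed %d pair %s-%s eps %g",
          seed, labs[i], labs[j], eps))
      }
    }
  }
})

test_that("the network edge set equals the exhaustive MST union (small n)", {
  for (seed in 1:15) {
    n <- sample(3:7, 1)
    W <- random_dissim(n, seed, integer = TRUE, max_int = 4L)  # force ties
    fit <- ultranet(W)
    expect_identical(edge_keys(fit$edges),
      edge_keys(all_mst_edge_union(W)), info = paste("seed", seed))
  }
})

test_that("network is connected with between n-1 and n(n-1)/2 edges", {
  for (seed in 1:10) {
    n <- sample(3:12, 1)
    W <- random_dissim(n, seed, integer = seed %% 2 == 0)
    fit <- ultranet(W)
    ne <- nrow(fit$edges)
    expect_gte(ne, n - 1)
    expect_lte(ne, n * (n - 1) / 2)
    g <- as_igraph_network(fit)
    expect_true(igraph::is_connected(g))
    # defining membership condition on every edge
    for (k in seq_len(ne))
      expect_equal(fit$edges$weight[k], fit$edges$wstar[k], tolerance = 1e-12)
  }
})

test_that("fit is idempotent: refitting on W* returns W* and the complete graph", {
  for (seed in c(2, 3)) {
    W <- random_dissim(7, seed, integer = seed %% 2 == 0)
    Ws <- ultranet(W)$Wstar
    refit <- ultranet(Ws)
    expect_equal(refit$Wstar, Ws, tolerance = 1e-14)
    expect_identical(nrow(refit$edges), 21L)  # every pair satisfies W* = W**
  }
})

test_that("result is invariant under vertex relabeling/reordering (any seed vertex)", {
  for (seed in c(1, 4)) {
    n <- 6
    W <- random_dissim(n, seed, integer = TRUE, max_int = 3L)
    base <- ultranet(W)
    for (first in seq_len(n)) {
      perm <- c(first, setdiff(seq_len(n), first))
      Wp <- W[perm, perm]
      fit <- ultranet(Wp)  # seed vertex = labels[perm][1]
      expect_equal(fit$Wstar[rownames(W), rownames(W)], base$Wstar,
        tolerance = 1e-14)
      expect_identical(edge_keys(fit$edges), edge_keys(base$edges))
    }
  }
})

test_that("paths within a single MST already realize all W* values", {
  for (seed in 1:5) {
    W <- random_dissim(7, seed)
    fit <- ultranet(W)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
      weighted = TRUE)
    mst <- igraph::as_data_frame(igraph::mst(g), what = "edges")
    names(mst)[1:2] <- c("u", "v")
    M <- closure_of_graph(rownames(W), mst)
    expect_equal(M, fit$Wstar, tolerance = 1e-12)
  }
})

test_that("bottleneck() looks up pair values and rejects unknown labels", {
  fit <- ultranet(canonical4())
  expect_identical(bottleneck(fit, "a", "d"), 3)
  expect_identical(bottleneck(fit, "b", "b"), 0)
  expect_error(bottleneck(fit, "a", "z"), class = "ultranet_lookup_error")
})

test_that("elementary-step counter grows quadratically", {
  ns <- c(40, 80, 160, 320)
  steps <- vapply(ns, function(n)
    ultranet(random_dissim(n, seed = n))$steps, 0)
  slope <- coef(lm(log(steps) ~ log(ns)))[[2]]
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})
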
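unit_triangle <- function() {
  data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"), weight = 1,
    stringsAsFactors = FALSE)
}

test_that("candidate search finds heavy triangles, strictly above threshold", {
  fit <- ultranet(canonical4())
  expect_identical(nrow(find_candidate_triangles(fit, 0)), 0L)  # a path
  tri <- unit_triangle()
  got <- find_candidate_triangles(tri, 2.5)
  expect_identical(nrow(got), 1L)
  expect_identical(unlist(got[1, 1:3], use.names = FALSE), c("a", "b", "c"))
  expect_identical(got$perimeter, 3)
  expect_identical(nrow(find_candidate_triangles(tri, 3)), 0L)  # strict ">"
})

test_that("candidates are ranked by perimeter, ties by label triple", {
  ed <- data.frame(
    u = c("a", "a", "b", "b", "c"),
    v = c("b", "c", "c", "d", "d"),
    weight = c(1, 1, 2, 1, 1), stringsAsFactors = FALSE)
  got <- find_candidate_triangles(ed, 0)
  expect_identical(got$perimeter, c(4, 4))
  expect_identical(got$a, c("a", "b"))  # tie broken lexicographically
})

test_that("median distances solve the three path equations", {
  med <- median_distances(4, 6, 8)
  expect_identical(unname(med), c(1, 3, 5))
  expect_identical(unname(median_distances(2, 2, 2)), c(1, 1, 1))
  # degenerate boundary of the triangle inequality: a zero-length edge
  expect_identical(unname(median_distances(1, 2, 3)), c(0, 1, 2))
  for (seed in 1:10) {
    set.seed(seed)
    s <- sort(runif(3, 1, 10))
    if (s[3] >= s[1] + s[2]) next
    med <- median_distances(s[1], s[2], s[3])
    expect_equal(med[["xu"]] + med[["xw"]], s[1], tolerance = 1e-12)
    expect_equal(med[["xu"]] + med[["xy"]], s[2], tolerance = 1e-12)
    expect_equal(med[["xw"]] + med[["xy"]], s[3], tolerance = 1e-12)
    expect_equal(sum(med), sum(s) / 2, tolerance = 1e-12)
  }
})

test_that("unit triangle at threshold 0 collapses to a half-weight star", {
  aug <- insert_artificial_vertices(unit_triangle(), 0)
  expect_identical(aug$artificial, "N1")
  expect_identical(aug$provenance$N1, c("a", "b", "c"))
  expect_identical(nrow(aug$edges), 3L)
  expect_true(all(aug$edges$weight == 0.5))
  expect_identical(sum(aug$edges$weight), 1.5)  # down from 3
  # corner-to-corner distances through N1 are preserved exactly
  wl <- structure(aug$edges$weight, names = edge_keys(aug$edges))
  star <- function(corner) wl[[paste("N1", corner, sep = "|")]]
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_identical(star(pr[1]) + star(pr[2]), 1)
})

test_that("trees pass through augmentation unchanged", {
  fit <- ultranet(canonical4(), augment_threshold = 0)
  expect_identical(fit$artificial, character(0))
  expect_identical(edge_keys(fit$graph), c("a|b", "b|c", "c|d"))
  for (seed in 1:5) {
    W <- random_dissim(8, seed)  # continuous weights: network is a tree a.s.
    fit <- ultranet(W, augment_threshold = 0)
    if (nrow(fit$edges) == 7L) expect_identical(fit$artificial, character(0))
  }
})

test_that("a shared edge is consumed by the heavier triangle only", {
  ed <- data.frame(
    u = c("a", "a", "b", "b", "c"),
    v = c("b", "c", "c", "d", "d"),
    weight = c(3, 3, 3, 1.4, 1.4), stringsAsFactors = FALSE)
  # perimeters: (a,b,c) = 9, (b,c,d) = 5.8; both exceed 5
  aug <- insert_artificial_vertices(ed, 5)
  expect_identical(aug$artificial, "N1")
  expect_identical(aug$provenance$N1, c("a", "b", "c"))
  expect_identical(length(aug$skipped), 1L)
  expect_identical(aug$skipped[[1]]$reason, "edge-consumed")
  expect_true(all(c("b|d", "c|d") %in% edge_keys(aug$edges)))
  expect_false("b|c" %in% edge_keys(aug$edges))
})

test_that("degenerate triangles are skipped with a warning", {
  ed <- data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"),
    weight = c(1, 2, 3), stringsAsFactors = FALSE)
  expect_warning(aug <- insert_artificial_vertices(ed, 0), "degenerate")
  expect_identical(aug$artificial, character(0))
  expect_identical(nrow(aug$edges), 3L)
  expect_identical(aug$skipped[[1]]$reason, "degenerate")
})

test_that("total weight never increases, and strictly drops on insertion", {
  for (seed in 1:10) {
    W <- random_dissim(7, seed, integer = TRUE, max_int = 3L)
    fit <- ultranet(W, delta = 1)  # relaxed nets carry triangles
    before <- sum(fit$edges$weight)
    aug <- suppressWarnings(insert_artificial_vertices(fit, 0))
    after <- sum(aug$edges$weight)
    expect_lte(after, before + 1e-12)
    if (length(aug$artificial) > 0) expect_lt(after, before)
  }
})

test_that("augmentation is independent of edge input order", {
  for (seed in 1:50) {
    W <- random_dissim(6, seed, integer = TRUE, max_int = 4L)
    fit <- ultranet(W, delta = 1)
    ed <- fit$edges[c("u", "v", "weight")]
    base <- suppressWarnings(insert_artificial_vertices(ed, 2))
    set.seed(seed + 1000)
    shuf <- ed[sample(nrow(ed)), , drop = FALSE]
    alt <- suppressWarnings(insert_artificial_vertices(shuf, 2))
    expect_identical(base$edges, alt$edges, info = paste("seed", seed))
    expect_identical(base$artificial, alt$artificial)
    expect_identical(base$provenance, alt$provenance)
  }
})
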
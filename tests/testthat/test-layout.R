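test_that("coarsening halves a path and nibbles a star at the hub", {
  p8 <- kruskal_forest(graph_from_edge_list(8, 0:6, 1:7, rep(0.1, 7)))
  lv <- coarsen_forest(p8, coarsest_size = 2)
  expect_equal(vapply(lv, function(x) x$n, integer(1)), c(8L, 4L, 2L))
  # star K_{1,6}: only one edge can be matched per level
  st <- kruskal_forest(graph_from_edge_list(7, rep(0, 6), 1:6, rep(0.1, 6)))
  lv2 <- coarsen_forest(st, coarsest_size = 2)
  expect_equal(vapply(lv2, function(x) x$n, integer(1)), 7:2)
  # single vertex: one-level hierarchy
  s1 <- kruskal_forest(graph_from_edge_list(1, integer(0), integer(0), numeric(0)))
  expect_length(coarsen_forest(s1), 1L)
})

test_that("layout is deterministic and places a single vertex at the origin", {
  s1 <- kruskal_forest(graph_from_edge_list(1, integer(0), integer(0), numeric(0)))
  l1 <- layout_forest(s1, layout_config(seed = 1))
  expect_equal(l1$coordinates, matrix(0, 1, 2))
  set.seed(3)
  sf <- random_spanning_forest(80)
  a <- layout_forest(sf, layout_config(seed = 5))
  b <- layout_forest(sf, layout_config(seed = 5))
  expect_identical(a$coordinates, b$coordinates)
  c_ <- layout_forest(sf, layout_config(seed = 6))
  expect_false(identical(a$coordinates, c_$coordinates))
})

test_that("a path lays out with distinct, comparably spaced vertices", {
  sf <- kruskal_forest(graph_from_edge_list(5, 0:3, 1:4, rep(0.2, 4)))
  lay <- layout_forest(sf, layout_config(seed = 3))
  xy <- lay$coordinates
  expect_equal(anyDuplicated(round(xy, 9)), 0L)
  d <- sqrt(rowSums((xy[1:4, ] - xy[2:5, ])^2))
  expect_lt(max(d) / min(d), 5)
})

test_that("no adjacent collisions, finite coordinates, energy descends", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(10:300, 1)
    sf <- random_spanning_forest(n)
    lay <- layout_forest(sf, layout_config(seed = rep))
    expect_true(all(is.finite(lay$coordinates)))
    e <- sf$edges
    d <- sqrt(rowSums((lay$coordinates[e$u + 1, , drop = FALSE] -
                         lay$coordinates[e$v + 1, , drop = FALSE])^2))
    expect_gt(min(d), 0)
    expect_lte(lay$energy_final, lay$energy_initial)
  }
})

test_that("disconnected forests are packed without overlap", {
  e <- data.frame(u = c(0, 1, 4, 5), v = c(1, 2, 5, 6), w = rep(0.3, 4))
  g <- graph_from_edge_list(8, e$u, e$v, e$w)   # {0,1,2}, {4,5,6}, {3}, {7}
  sf <- kruskal_forest(g)
  lay <- layout_forest(sf, layout_config(seed = 2))
  comp <- sf$components
  expect_equal(max(comp) + 1L, 4L)
  # bounding boxes of distinct components do not intersect
  boxes <- lapply(0:3, function(c_) {
    xy <- lay$coordinates[comp == c_, , drop = FALSE]
    c(range(xy[, 1]), range(xy[, 2]))
  })
  for (i in 1:3) for (j in (i + 1):4) {
    a <- boxes[[i]]; b <- boxes[[j]]
    disjoint <- a[2] < b[1] || b[2] < a[1] || a[4] < b[3] || b[4] < a[3]
    expect_true(disjoint)
  }
})

test_that("quadtree approximation stays close to exact repulsion", {
  skip_if_not_installed("vegan")
  set.seed(19)
  ratios <- vapply(1:6, function(s) {
    n <- sample(20:64, 1)
    sf <- random_spanning_forest(n)
    lex <- layout_forest(sf, layout_config(theta = 0, seed = s))
    lbh <- layout_forest(sf, layout_config(theta = 0.9, seed = s))
    pr <- vegan::procrustes(lex$coordinates, lbh$coordinates)
    sqrt(mean(stats::residuals(pr)^2)) / max(stats::dist(lex$coordinates))
  }, numeric(1))
  expect_lt(mean(ratios), 0.10)
})

test_that("scale_layout rescales affinely and is idempotent", {
  sf <- kruskal_forest(graph_from_edge_list(2, 0, 1, 0.5))
  lay <- layout_forest(sf, layout_config(seed = 1))
  lay$coordinates <- matrix(c(0, 2, 0, 0), ncol = 2)
  s1 <- scale_layout(lay, 1)
  expect_equal(s1$coordinates, matrix(c(0, 1, 0, 0), ncol = 2))
  expect_equal(scale_layout(s1, 1)$coordinates, s1$coordinates)
  # distance ratios preserved
  lay$coordinates <- matrix(stats::runif(20), ncol = 2)
  s2 <- scale_layout(lay, 7)
  r0 <- as.vector(stats::dist(lay$coordinates))
  r1 <- as.vector(stats::dist(s2$coordinates))
  expect_lt(max(abs(r1 / r0 - r1[1] / r0[1])), 1e-9)
  lay$coordinates <- matrix(1, 4, 2)
  expect_error(scale_layout(lay, 1), class = "mstmap_degenerate_layout")
})

test_that("layout rejects invalid configuration and empty input", {
  expect_error(layout_config(p = 0), class = "mstmap_invalid_parameter")
  expect_error(layout_config(theta = 3), class = "mstmap_invalid_parameter")
  expect_error(layout_config(coarsest_size = 1), class = "mstmap_invalid_parameter")
  sf <- kruskal_forest(graph_from_edge_list(1, integer(0), integer(0), numeric(0)))
  sf$n <- 0L
  expect_error(layout_forest(sf, layout_config()), class = "mstmap_empty_input")
})
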
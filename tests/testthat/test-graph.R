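test_that("identical records connect at distance zero, edges canonical", {
  fam <- hash_family(64, seed = 2)
  sets <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  f <- lsh_forest(64, 8)
  forest_add(f, minhash_signatures(sets, fam))
  forest_index(f)
  g <- build_knn_graph(f, k = 2, kc = 2)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$edges$w, rep(0, 3))
  expect_true(all(g$edges$u < g$edges$v))
  expect_equal(anyDuplicated(paste(g$edges$u, g$edges$v)), 0L)
})

test_that("knn-graph edge weights approximate exact Jaccard distances", {
  syn <- generate_clustered_sets(120, n_clusters = 3, universe = 1024,
                                 core_size = 48, seed = 23)
  fam <- hash_family(512, seed = 31)
  f <- lsh_forest(512, 8)
  forest_add(f, minhash_signatures(syn$sets, fam))
  forest_index(f)
  g <- build_knn_graph(f, k = 5, kc = 5)
  D <- jaccard_distance_matrix(syn$sets)
  errs <- abs(g$edges$w - D[cbind(g$edges$u + 1, g$edges$v + 1)])
  expect_lt(max(errs), 0.10)
})

test_that("edge-list input is canonicalized, deduplicated and validated", {
  g <- graph_from_edge_list(3, 1, 0, 0.5)
  expect_equal(g$edges$u, 0)
  expect_equal(g$edges$v, 1)
  g2 <- graph_from_edge_list(2, c(0, 1), c(1, 0), c(0.5, 0.5))
  expect_equal(nrow(g2$edges), 1L)
  expect_error(graph_from_edge_list(2, 0, 0, 0.1), class = "mstmap_invalid_edge")
  expect_error(graph_from_edge_list(2, 0, 2, 0.1), class = "mstmap_invalid_edge")
  expect_error(graph_from_edge_list(2, 0, 1, -0.1), class = "mstmap_invalid_edge")
  expect_error(graph_from_edge_list(2, c(0, 1), c(1, 0), c(0.5, 0.6)),
               class = "mstmap_inconsistent_input")
})

test_that("connected components are numbered by smallest member", {
  g <- graph_from_edge_list(3, 0, 1, 1)
  expect_equal(connected_components(g), c(0L, 0L, 1L))
  g2 <- graph_from_edge_list(4, integer(0), integer(0), numeric(0))
  expect_equal(connected_components(g2), 0:3)
  g3 <- graph_from_edge_list(5, 0:3, 1:4, rep(1, 4))
  expect_equal(connected_components(g3), rep(0L, 5))
})

test_that("kruskal drops the heaviest edge of a cycle and keeps trees fixed", {
  tri <- graph_from_edge_list(3, c(0, 1, 0), c(1, 2, 2), c(0.2, 0.3, 0.9))
  sf <- kruskal_forest(tri)
  expect_equal(sf$edges$u, c(0, 1))
  expect_equal(sf$edges$v, c(1, 2))
  expect_equal(sum(sf$edges$w), 0.5)
  # a tree is its own spanning forest, and kruskal is idempotent
  sf2 <- kruskal_forest(sf)
  expect_equal(sf2$edges, sf$edges)
})

test_that("kruskal is optimal on random graphs (enumeration + igraph oracles)", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    e <- random_connected_graph(n, extra = sample(1:3, 1))
    g <- graph_from_edge_list(n, e$u, e$v, e$w)
    sf <- kruskal_forest(g)
    expect_equal(sum(sf$edges$w), enum_mst_weight(n, g$edges))
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g$edges$u + 1, to = g$edges$v + 1),
      directed = FALSE, vertices = data.frame(name = 1:n))
    igraph::E(ig)$weight <- g$edges$w
    expect_equal(sum(sf$edges$w),
                 sum(igraph::E(igraph::mst(ig))$weight))
  }
})

test_that("forest structure is conserved on disconnected random graphs", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(6:40, 1)
    m <- sample(0:(2 * n), 1)
    u <- sample.int(n, m, replace = TRUE) - 1L
    v <- sample.int(n, m, replace = TRUE) - 1L
    keep <- u != v
    uu <- pmin(u[keep], v[keep]); vv <- pmax(u[keep], v[keep])
    dup <- duplicated(paste(uu, vv))
    g <- graph_from_edge_list(n, uu[!dup], vv[!dup], round(runif(sum(!dup)), 3))
    sf <- kruskal_forest(g)
    comp <- connected_components(g)
    expect_equal(nrow(sf$edges), n - (max(comp) + 1L))
    expect_equal(sf$components, comp)
    # isolated vertices survive as singletons
    deg <- tabulate(c(g$edges$u, g$edges$v) + 1L, nbins = n)
    for (iso in which(deg == 0L))
      expect_equal(sum(sf$components == sf$components[iso]), 1L)
  }
})

test_that("the cut property holds on random bipartitions", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 10
    e <- random_connected_graph(n, extra = 5)
    e$w <- runif(nrow(e))          # continuous: ties have measure zero
    g <- graph_from_edge_list(n, e$u, e$v, e$w)
    sf <- kruskal_forest(g)
    side <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(side) || !any(side)) side[1] <- !side[1]
    crossing <- xor(side[g$edges$u + 1], side[g$edges$v + 1])
    cross_tree <- xor(side[sf$edges$u + 1], side[sf$edges$v + 1])
    if (any(crossing) && any(cross_tree)) {
      expect_lte(min(g$edges$w[crossing]), min(sf$edges$w[cross_tree]))
    }
  }
})
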
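test_that("topological distances are BFS hop counts with Inf across components", {
  sf <- kruskal_forest(graph_from_edge_list(5, c(0, 1, 3), c(1, 2, 4),
                                            rep(0.1, 3)))
  d0 <- topological_distances(sf, 0)
  expect_equal(d0, c(0, 1, 2, Inf, Inf))
  expect_equal(topological_distances(sf, 2)[3], 0)
  expect_error(topological_distances(sf, 5), class = "mstmap_range_error")
  expect_error(topological_distances(sf, -1), class = "mstmap_range_error")
})

test_that("true nearest neighbors follow exact Jaccard with id tie-break", {
  sets <- list(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),   # 0
               c(1, 2, 3, 4, 5, 6, 7, 8, 9, 11),   # 1: J(0,1) = 9/11
               c(100, 101, 102))                   # 2: far from both
  nn <- true_nearest_neighbors(sets)
  expect_equal(nn[1:2], c(1L, 0L))
  expect_equal(nn[3], 0L)        # all distances 1: tie broken by smallest id
  # duplicated point: mutual nearest at distance 0
  sets2 <- list(c(1, 2), c(1, 2), c(9, 10, 11))
  expect_equal(true_nearest_neighbors(sets2)[1:2], c(1L, 0L))
})

test_that("an embedding that reproduces the original ordering ranks all at 1", {
  # three records with strict distance ordering: d(A,B) < d(B,C) < d(A,C),
  # reproduced by collinear positions 0, 1, 2.5
  sets <- list(0:9, c(0:7, 20, 21), c(0:4, 20, 21, 30:32))
  nn <- true_nearest_neighbors(sets)
  expect_equal(nn, c(1L, 0L, 1L))
  lay <- structure(list(coordinates = cbind(c(0, 1, 2.5), c(0, 0, 0))),
                   class = "mst_layout")
  rep_ <- nn_preservation(sets, layout = lay, metric = "euclidean", true_nn = nn)
  expect_equal(rep_$ranks, rep(1L, 3))
  expect_equal(rep_$summary$fraction_rank1, 1)
})

test_that("euclidean ranks are invariant to rotation and scaling", {
  set.seed(6)
  sets <- replicate(30, sample(0:80, 12), simplify = FALSE)
  xy <- matrix(stats::runif(60), ncol = 2)
  lay <- structure(list(coordinates = xy), class = "mst_layout")
  r1 <- nn_preservation(sets, layout = lay, metric = "euclidean")
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  lay2 <- structure(list(coordinates = 3.7 * xy %*% rot + 11),
                    class = "mst_layout")
  r2 <- nn_preservation(sets, layout = lay2, metric = "euclidean")
  expect_equal(r1$ranks, r2$ranks)
})

test_that("random embeddings rank the true neighbor near n/2 on average", {
  set.seed(9)
  n <- 100
  sets <- replicate(n, sample(0:300, 15), simplify = FALSE)
  tnn <- true_nearest_neighbors(sets)
  means <- vapply(1:20, function(s) {
    xy <- matrix(stats::runif(2 * n), ncol = 2)
    lay <- structure(list(coordinates = xy), class = "mst_layout")
    nn_preservation(sets, layout = lay, metric = "euclidean",
                    true_nn = tnn)$summary$mean
  }, numeric(1))
  expect_lt(abs(mean(means) - n / 2), 0.15 * (n / 2))
})

test_that("the fitted tree map preserves locality far better than chance", {
  syn <- generate_clustered_sets(200, n_clusters = 4, universe = 2048,
                                 core_size = 64, seed = 15)
  fit <- mstmap(syn$sets, d = 256, l = 8, k = 8, kc = 5, seed = 15)
  tnn <- true_nearest_neighbors(syn$sets)
  topo <- nn_preservation(syn$sets, forest = fit$forest,
                          metric = "topological", true_nn = tnn)
  eucl <- nn_preservation(syn$sets, layout = fit$layout,
                          metric = "euclidean", true_nn = tnn)
  base <- structure(list(coordinates = matrix(stats::runif(400), ncol = 2)),
                    class = "mst_layout")
  rnd <- nn_preservation(syn$sets, layout = base, metric = "euclidean",
                         true_nn = tnn)
  expect_lt(topo$summary$median, rnd$summary$median)
  expect_lt(eucl$summary$median, rnd$summary$median)
})

test_that("inconsistent inputs are rejected", {
  sets <- list(c(1, 2), c(2, 3), c(3, 4))
  sf <- kruskal_forest(graph_from_edge_list(2, 0, 1, 0.1))
  expect_error(nn_preservation(sets, forest = sf, metric = "topological"),
               class = "mstmap_inconsistent_input")
  lay <- structure(list(coordinates = matrix(0, 2, 2)), class = "mst_layout")
  expect_error(nn_preservation(sets, layout = lay, metric = "euclidean"),
               class = "mstmap_inconsistent_input")
})
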
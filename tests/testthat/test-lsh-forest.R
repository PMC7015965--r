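test_that("forest creation validates d and l", {
  f <- lsh_forest(512, 8)
  expect_equal(f$l, 8L)
  expect_equal(f$depth, 64L)
  expect_error(lsh_forest(512, 7), class = "mstmap_invalid_parameter")
  f2 <- lsh_forest(4, 4)
  expect_equal(f2$depth, 1L)
})

test_that("adding signatures enforces ids and lineage", {
  fam <- hash_family(64, seed = 1)
  f <- lsh_forest(64, 8)
  forest_add(f, minhash_signature(c(1, 2, 3), fam), id = 0)
  expect_equal(forest_size(f), 1L)
  expect_error(forest_add(f, minhash_signature(c(9, 10), fam), id = 0),
               class = "mstmap_duplicate_id")
  wrong_d <- hash_family(32, seed = 1)
  expect_error(forest_add(f, minhash_signature(c(1, 2), wrong_d), id = 1),
               class = "mstmap_incompatible_signature")
  other_seed <- hash_family(64, seed = 2)
  expect_error(forest_add(f, minhash_signature(c(1, 2), other_seed), id = 1),
               class = "mstmap_incompatible_signature")
})

test_that("indexing is required, idempotent, and empty forests refuse", {
  fam <- hash_family(64, seed = 1)
  f <- lsh_forest(64, 8)
  expect_error(forest_index(f), class = "mstmap_empty_index")
  sets <- list(c(1, 2, 3), c(2, 3, 4), c(7, 8))
  forest_add(f, minhash_signatures(sets, fam))
  q <- minhash_signature(c(1, 2, 3), fam)
  expect_error(forest_query(f, q, k = 1), class = "mstmap_not_indexed")
  forest_index(f)
  state1 <- lapply(f$trees, identity)
  forest_index(f)
  expect_identical(lapply(f$trees, identity), state1)
  for (t in seq_along(f$trees))
    expect_length(f$trees[[t]]$ord, length(sets))
})

test_that("self-queries and k >= n contracts hold", {
  fam <- hash_family(64, seed = 4)
  sets <- list(c(1, 2, 3), c(2, 3, 4), c(1, 2, 3, 4), c(50, 60))
  f <- lsh_forest(64, 8)
  forest_add(f, minhash_signatures(sets, fam))
  forest_index(f)
  res <- forest_query(f, minhash_signature(sets[[2]], fam), k = 4)
  expect_equal(res$id[1], 1)
  expect_equal(res$distance[1], 0)
  res2 <- forest_query(f, minhash_signature(sets[[2]], fam), k = 10,
                       exclude_self = TRUE, self_id = 1)
  expect_equal(nrow(res2), 3L)
  expect_false(1 %in% res2$id)
  # distances non-decreasing
  expect_true(all(diff(res$distance) >= 0))
  expect_true(all(diff(res2$distance) >= 0))
})

test_that("query results are invariant to insertion order", {
  fam <- hash_family(128, seed = 6)
  set.seed(8)
  sets <- replicate(40, sample(0:200, sample(5:25, 1)), simplify = FALSE)
  sigs <- minhash_signatures(sets, fam)
  f1 <- lsh_forest(128, 8)
  forest_add(f1, sigs, ids = 0:39)
  forest_index(f1)
  perm <- sample(40)
  f2 <- lsh_forest(128, 8)
  perm_sigs <- structure(list(values = sigs$values[, perm], flavor = "plain",
                              d = 128L, seed = sigs$seed), class = "mh_signatures")
  forest_add(f2, perm_sigs, ids = perm - 1)
  forest_index(f2)
  for (i in c(1, 17, 33)) {
    q <- minhash_signature(sets[[i]], fam)
    expect_identical(forest_query(f1, q, k = 5), forest_query(f2, q, k = 5))
  }
})

test_that("recall against the exact oracle does not decrease with kc", {
  syn <- generate_clustered_sets(300, n_clusters = 3, universe = 1024,
                                 core_size = 48, seed = 17)
  fam <- hash_family(256, seed = 99)
  f <- lsh_forest(256, 8)
  forest_add(f, minhash_signatures(syn$sets, fam))
  forest_index(f)
  D <- jaccard_distance_matrix(syn$sets)
  recalls <- vapply(c(1, 2, 5), function(kc) {
    hits <- vapply(seq(1, 300, by = 3), function(i) {
      res <- forest_query(f, minhash_signature(syn$sets[[i]], fam), k = 10,
                          kc = kc, exclude_self = TRUE, self_id = i - 1)
      length(intersect(res$id, brute_knn(D, i, 10))) / 10
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  expect_gt(recalls[3], recalls[1])
})

test_that("serialized index size grows with d and l, and round-trips", {
  fam64 <- hash_family(64, seed = 2)
  fam128 <- hash_family(128, seed = 2)
  set.seed(5)
  sets <- replicate(30, sample(0:500, 10), simplify = FALSE)
  mk <- function(d, l, fam) {
    f <- lsh_forest(d, l)
    forest_add(f, minhash_signatures(sets, fam))
    forest_index(f)
    f
  }
  sz <- function(f) { p <- tempfile(); forest_save(f, p); file.size(p) }
  expect_lt(sz(mk(64, 8, fam64)), sz(mk(128, 8, fam128)))
  expect_lt(sz(mk(64, 4, fam64)), sz(mk(64, 8, fam64)))
  # save/load preserves query results
  f <- mk(128, 8, fam128)
  path <- tempfile()
  forest_save(f, path)
  g <- forest_load(path)
  q <- minhash_signature(sets[[3]], fam128)
  expect_identical(forest_query(f, q, k = 5), forest_query(g, q, k = 5))
})
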
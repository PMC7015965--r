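# Independent oracles and fixture builders used across the suite.

# Exhaustive minimum-spanning-tree weight for a CONNECTED graph: try every
# (n-1)-subset of edges; any acyclic (n-1)-subset is a spanning tree.
enum_mst_weight <- function(n, edges) {
  m <- nrow(edges)
  stopifnot(m >= n - 1)
  best <- Inf
  combos <- utils::combn(m, n - 1L)
  for (j in seq_len(ncol(combos))) {
    sel <- combos[, j]
    parent <- seq_len(n)
    ok <- TRUE
    for (r in sel) {
      a <- edges$u[r] + 1L
      while (parent[a] != a) a <- parent[a]
      b <- edges$v[r] + 1L
      while (parent[b] != b) b <- parent[b]
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) {
      w <- sum(edges$w[sel])
      if (w < best) best <- w
    }
  }
  best
}

# Random connected graph: random recursive tree plus extra distinct edges.
random_connected_graph <- function(n, extra = 3L) {
  u <- integer(n - 1L)
  for (i in 2:n) u[i - 1L] <- sample.int(i - 1L, 1L) - 1L
  e <- data.frame(u = u, v = 1:(n - 1L), w = 0)
  have <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
  tries <- 0L
  while (extra > 0L && tries < 50L) {
    a <- sample.int(n, 1L) - 1L; b <- sample.int(n, 1L) - 1L
    key <- paste(min(a, b), max(a, b))
    if (a != b && !(key %in% have)) {
      e <- rbind(e, data.frame(u = min(a, b), v = max(a, b), w = 0))
      have <- c(have, key)
      extra <- extra - 1L
    }
    tries <- tries + 1L
  }
  e$w <- round(stats::runif(nrow(e)), 3)
  e
}

# Random tree as an edge data.frame (random recursive attachment).
random_tree_edges <- function(n) {
  u <- integer(n - 1L)
  for (i in 2:n) u[i - 1L] <- sample.int(i - 1L, 1L) - 1L
  data.frame(u = u, v = 1:(n - 1L), w = stats::runif(n - 1L))
}

random_spanning_forest <- function(n) {
  e <- random_tree_edges(n)
  kruskal_forest(graph_from_edge_list(n, e$u, e$v, e$w))
}

# A pair of item sets with an exact target Jaccard similarity: both of
# size s, sharing c = round(2 s J / (1 + J)) items.
make_jaccard_pair <- function(J, s = 100L, salt = 0L) {
  c_ <- round(2 * s * J / (1 + J))
  shared <- salt * 10000L + seq_len(c_)
  a <- c(shared, salt * 10000L + 5000L + seq_len(s - c_))
  b <- c(shared, salt * 10000L + 7000L + seq_len(s - c_))
  list(a = a, b = b, jaccard = c_ / (2 * s - c_))
}

# Brute-force exact-Jaccard k-NN ids (0-based) for one record.
brute_knn <- function(dmat, i, k) {
  d <- dmat[i, ]
  d[i] <- Inf
  order(d, seq_along(d))[seq_len(k)] - 1L
}
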
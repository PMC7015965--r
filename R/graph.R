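#' Undirected weighted neighbor graph
#'
#' Container for the c-approximate k-NN graph (phase II): vertex count
#' `n` and a canonical edge table with `u < v`, 0-based vertex ids and
#' non-negative weights (Jaccard distances on the indexing path;
#' arbitrary non-negative weights for external edge lists).
#'
#' @param n vertex count.
#' @param edges `data.frame` with columns `u`, `v`, `w`.
#' @return an object of class `"neighbor_graph"`.
#' @keywords internal
new_neighbor_graph <- function(n, edges) {
  structure(list(n = as.integer(n),
                 edges = edges[order(edges$u, edges$v), , drop = FALSE]),
            class = "neighbor_graph")
}

#' @export
#' @method print neighbor_graph
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("Neighbor graph: %d vertices, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Build the c-approximate k-NN graph from an indexed LSH forest
#'
#' Phase II: every indexed record is queried for its `k` approximate
#' nearest neighbors (self excluded) with the augmented query, and each
#' result becomes an undirected edge weighted by the estimated Jaccard
#' distance of its endpoints.  Edges discovered from both endpoints are
#' stored once (canonical `u < v`); records whose neighbors are all at
#' distance 1 can remain isolated.
#'
#' Record ids must be the integers `0 .. n-1` on this path (they index
#' vertices of the graph).
#'
#' @param f an indexed [lsh_forest()].
#' @param k neighbors per record.
#' @param kc augmentation factor of the candidate pool.
#' @return a `"neighbor_graph"`.
#' @export
build_knn_graph <- function(f, k, kc = 10) {
  if (!f$indexed) mm_stop("not_indexed", "forest must be indexed")
  k <- check_count(k, "k")
  kc <- check_count(kc, "kc")
  n <- f$n
  ids <- f$ids[seq_len(n)]
  if (!identical(sort(ids), as.numeric(seq_len(n) - 1)))
    mm_stop("inconsistent_input", "record ids must be 0..n-1 for graph construction")
  W <- min(n, k * kc)
  us <- vector("list", n); vs <- vector("list", n); ws <- vector("list", n)
  for (col in seq_len(n)) {
    self <- ids[col]
    pool <- .gather_pool(f, record_col = col, poolcap = k * kc + 1L, W = W)
    pool <- setdiff(pool, self)
    res <- .rerank(f, f$S[, col], pool, k)
    us[[col]] <- pmin(self, res$id)
    vs[[col]] <- pmax(self, res$id)
    ws[[col]] <- res$distance
  }
  u <- unlist(us); v <- unlist(vs); w <- unlist(ws)
  # symmetric discovery: keep the first-computed weight per (u, v)
  key <- u * n + v
  keep <- !duplicated(key)
  new_neighbor_graph(n, data.frame(u = u[keep], v = v[keep], w = w[keep]))
}

#' Neighbor graph from an explicit edge list
#'
#' Bypass for phases I-II: accepts an arbitrary undirected weighted graph.
#' Edges are canonicalized to `u < v` and deduplicated; a duplicate pair
#' carrying a different weight is an error.
#'
#' @param n vertex count.
#' @param u,v 0-based endpoint vertex ids.
#' @param w non-negative edge weights.
#' @return a `"neighbor_graph"`.
#' @export
graph_from_edge_list <- function(n, u, v, w) {
  n <- check_count(n, "n")
  if (length(u) != length(v) || length(u) != length(w))
    mm_stop("inconsistent_input", "u, v, w must have equal length")
  if (length(u) > 0L) {
    if (any(u < 0) || any(v < 0) || any(u >= n) || any(v >= n))
      mm_stop("invalid_edge", "vertex id out of range")
    if (any(u == v)) mm_stop("invalid_edge", "self-loops are not allowed")
    if (any(w < 0)) mm_stop("invalid_edge", "weights must be non-negative")
  }
  uu <- pmin(u, v); vv <- pmax(u, v)
  key <- uu * n + vv
  first <- !duplicated(key)
  if (!all(w == w[first][match(key, key[first])]))
    mm_stop("inconsistent_input", "duplicate edge with conflicting weights")
  new_neighbor_graph(n, data.frame(u = uu[first], v = vv[first], w = w[first]))
}

# Union-find with path compression (iterative) and union by rank.
.uf_new <- function(n) list(parent = seq_len(n), rank = integer(n))

.uf_find <- function(uf, i) {
  root <- i
  while (uf$parent[root] != root) root <- uf$parent[root]
  while (uf$parent[i] != root) {
    nxt <- uf$parent[i]
    uf$parent[i] <- root
    i <- nxt
  }
  list(uf = uf, root = root)
}

.uf_union <- function(uf, a, b) {
  fa <- .uf_find(uf, a); uf <- fa$uf
  fb <- .uf_find(uf, b); uf <- fb$uf
  ra <- fa$root; rb <- fb$root
  if (ra == rb) return(list(uf = uf, merged = FALSE))
  if (uf$rank[ra] < uf$rank[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
  uf$parent[rb] <- ra
  if (uf$rank[ra] == uf$rank[rb]) uf$rank[ra] <- uf$rank[ra] + 1L
  list(uf = uf, merged = TRUE)
}

#' Connected components of a neighbor graph
#'
#' @param g a `"neighbor_graph"` (or `"spanning_forest"`).
#' @return integer vector of 0-based component labels, one per vertex;
#'   components are numbered by their smallest contained vertex id,
#'   contiguously from 0.
#' @export
connected_components <- function(g) {
  n <- g$n
  uf <- .uf_new(n)
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    uf <- .uf_union(uf, e$u[i] + 1L, e$v[i] + 1L)$uf
  }
  roots <- integer(n)
  for (i in seq_len(n)) {
    fr <- .uf_find(uf, i); uf <- fr$uf; roots[i] <- fr$root
  }
  match(roots, unique(roots)) - 1L
}

#' Minimum spanning forest by Kruskal's algorithm
#'
#' Phase III: edges are scanned in ascending `(w, u, v)` order and joined
#' through a union-find structure (path compression + union by rank),
#' yielding, per connected component, a spanning tree of minimum total
#' weight.  Disconnected input is allowed; isolated vertices persist as
#' singleton components.  The `(w, u, v)` total order makes the result
#' unique and bit-reproducible.
#'
#' @param g a `"neighbor_graph"`.
#' @return an object of class `"spanning_forest"`: vertex count `n`, the
#'   tree edge table `edges`, and 0-based `components` labels.
#' @export
kruskal_forest <- function(g) {
  if (!inherits(g, c("neighbor_graph", "spanning_forest")))
    mm_stop("invalid_parameter", "'g' must be a neighbor_graph")
  n <- g$n
  e <- g$edges
  o <- order(e$w, e$u, e$v)
  uf <- .uf_new(n)
  take <- logical(nrow(e))
  for (i in o) {
    res <- .uf_union(uf, e$u[i] + 1L, e$v[i] + 1L)
    uf <- res$uf
    take[i] <- res$merged
  }
  tree <- e[take, , drop = FALSE]
  tree <- tree[order(tree$u, tree$v), , drop = FALSE]
  rownames(tree) <- NULL
  sf <- structure(list(n = n, edges = tree, components = NULL),
                  class = c("spanning_forest", "neighbor_graph"))
  sf$components <- connected_components(sf)
  sf
}

#' @export
#' @method print spanning_forest
print.spanning_forest <- function(x, ...) {
  cat(sprintf("Spanning forest: %d vertices, %d tree edges, %d component%s\n",
              x$n, nrow(x$edges), max(x$components) + 1L,
              if (max(x$components) == 0L) "" else "s"))
  invisible(x)
}
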
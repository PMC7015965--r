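#' LSH forest index over MinHash signatures
#'
#' Phase I of the pipeline: an index of `l` prefix trees over signature
#' components.  Tree `t` is keyed on the `d / l` consecutive signature
#' components `[t * d/l, (t+1) * d/l)`; each tree is realized as a sorted
#' key array with binary search rather than a pointer trie.  The forest
#' is a mutable reference object: [forest_add()] and [forest_index()]
#' update it in place.
#'
#' @param d signature length; must be divisible by `l`.
#' @param l number of prefix trees.
#' @return an object of class `"lsh_forest"`.
#' @examples
#' fam <- hash_family(64, seed = 1)
#' f <- lsh_forest(64, 8)
#' forest_add(f, minhash_signature(c(1, 2, 3), fam), id = 0)
#' forest_add(f, minhash_signature(c(2, 3, 4), fam), id = 1)
#' forest_index(f)
#' forest_query(f, minhash_signature(c(1, 2, 3), fam), k = 2)
#' @export
lsh_forest <- function(d, l) {
  d <- check_count(d, "d")
  l <- check_count(l, "l")
  if (d %% l != 0L)
    mm_stop("invalid_parameter", "d must be divisible by l")
  f <- new.env(parent = emptyenv())
  f$d <- d; f$l <- l; f$depth <- d %/% l
  f$flavor <- NULL; f$sig_seed <- NULL
  f$S <- matrix(numeric(0), nrow = d, ncol = 0)
  f$ids <- numeric(0)
  f$n <- 0L
  f$indexed <- FALSE
  f$trees <- NULL
  class(f) <- "lsh_forest"
  f
}

#' @export
#' @method print lsh_forest
print.lsh_forest <- function(x, ...) {
  cat(sprintf("LSH forest: d = %d, l = %d (depth %d), %d entr%s, %sindexed\n",
              x$d, x$l, x$depth, x$n, if (x$n == 1L) "y" else "ies",
              if (x$indexed) "" else "not "))
  invisible(x)
}

#' Number of records stored in a forest
#' @param f an [lsh_forest()].
#' @return integer count.
#' @export
forest_size <- function(f) f$n

.check_lineage <- function(f, flavor, d, seed) {
  if (d != f$d)
    mm_stop("incompatible_signature", "signature length does not match forest d")
  if (is.null(f$flavor)) {
    f$flavor <- flavor
    f$sig_seed <- seed
  } else if (!identical(f$flavor, flavor) || !identical(f$sig_seed, seed)) {
    mm_stop("incompatible_signature",
            "signature flavor/seed lineage does not match forest contents")
  }
  invisible(NULL)
}

.grow <- function(f, add) {
  need <- f$n + add
  cap <- ncol(f$S)
  if (need > cap) {
    newcap <- max(need, 2L * max(cap, 4L))
    S2 <- matrix(NA_real_, nrow = f$d, ncol = newcap)
    if (f$n > 0L) S2[, seq_len(f$n)] <- f$S[, seq_len(f$n)]
    f$S <- S2
  }
  invisible(NULL)
}

#' Add signatures to an LSH forest
#'
#' Accepts a single signature or a batch; record ids default to the next
#' 0-based integers.  Adding clears the indexed flag; call
#' [forest_index()] again before querying.
#'
#' @param f an [lsh_forest()].
#' @param x an `"mh_signature"` or `"mh_signatures"` object whose flavor,
#'   `d` and seed lineage match the forest contents.
#' @param id,ids record identifier(s); must be unique within the forest.
#' @return the forest, invisibly.
#' @export
forest_add <- function(f, x, id = NULL, ids = NULL) {
  if (inherits(x, "mh_signature")) {
    vals <- matrix(x$values, ncol = 1)
    new_ids <- if (!is.null(id)) id else if (!is.null(ids)) ids else f$n
  } else if (inherits(x, "mh_signatures")) {
    vals <- x$values
    new_ids <- if (!is.null(ids)) ids else seq.int(f$n, length.out = ncol(vals))
  } else {
    mm_stop("invalid_parameter", "'x' must be a signature or signature batch")
  }
  .check_lineage(f, x$flavor, x$d, x$seed)
  new_ids <- as.numeric(new_ids)
  if (length(new_ids) != ncol(vals))
    mm_stop("inconsistent_input", "one id per signature required")
  if (anyDuplicated(new_ids) || any(new_ids %in% f$ids[seq_len(f$n)]))
    mm_stop("duplicate_id", "record id already present in forest")
  .grow(f, ncol(vals))
  f$S[, f$n + seq_len(ncol(vals))] <- vals
  f$ids <- c(f$ids[seq_len(f$n)], new_ids)
  f$n <- f$n + ncol(vals)
  f$indexed <- FALSE
  f$trees <- NULL
  invisible(f)
}

# First index at which two equal-length key vectors differ, minus one;
# `depth` if identical.
.lcp2 <- function(a, b, depth) {
  w <- which(a != b)
  if (length(w) == 0L) depth else w[1L] - 1L
}

#' Build the sorted prefix-tree arrays of a forest
#'
#' Sorts, for each of the `l` trees, all stored keys lexicographically
#' (ties broken by record id) and precomputes the longest-common-prefix
#' lengths of adjacent sorted keys.  Idempotent; required before
#' [forest_query()].
#'
#' @param f an [lsh_forest()].
#' @return the forest, invisibly.
#' @export
forest_index <- function(f) {
  if (f$n == 0L) mm_stop("empty_index", "cannot index an empty forest")
  if (f$indexed) return(invisible(f))
  n <- f$n
  depth <- f$depth
  trees <- vector("list", f$l)
  for (t in seq_len(f$l)) {
    rows <- (t - 1L) * depth + seq_len(depth)
    keycols <- lapply(rows, function(r) f$S[r, seq_len(n)])
    ord <- do.call(order, c(keycols, list(f$ids[seq_len(n)])))
    K <- f$S[rows, ord, drop = FALSE]
    if (n > 1L) {
      fails <- rbind(K[, -1L, drop = FALSE] != K[, -n, drop = FALSE], TRUE)
      lcp <- max.col(t(fails), ties.method = "first") - 1L
    } else lcp <- integer(0)
    rank <- integer(n); rank[ord] <- seq_len(n)
    trees[[t]] <- list(ord = ord, lcp = lcp, rank = rank)
  }
  f$trees <- trees
  f$indexed <- TRUE
  invisible(f)
}

# Lexicographic lower bound of query key `qk` within tree `t`'s sorted
# order: the first position whose key is not less than `qk`.
.lex_lower_bound <- function(f, t, qk, rows) {
  tr <- f$trees[[t]]
  lo <- 1L; hi <- f$n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    v <- f$S[rows, tr$ord[mid]]
    w <- which(v != qk)
    if (length(w) > 0L && v[w[1L]] < qk[w[1L]]) lo <- mid + 1L else hi <- mid
  }
  lo
}

# Candidate gathering shared by forest_query() and build_knn_graph().
#
# Entries sharing a length-q prefix with the query form a contiguous run
# around its (insertion) position in each tree's sorted order, so the
# descending-prefix-depth scan of the augmented query equals an outward
# expansion whose per-entry prefix length is a running minimum of the
# adjacent-LCP array.  Depth levels are consumed in descending order and
# the level at which the pool first reaches `poolcap` distinct ids is
# included in full (no within-level truncation); per-tree windows extend
# in chunks of `W` only while their edge running-min can still reach the
# stopping level.  Returns the candidate id vector.
.gather_pool <- function(f, qvals = NULL, record_col = NULL, poolcap, W) {
  n <- f$n
  depth <- f$depth
  l <- f$l
  # per-tree expansion state
  pos <- integer(l); lcp0r <- integer(l); lcp0l <- integer(l)
  taken_r <- integer(l); taken_l <- integer(l)
  min_r <- integer(l); min_l <- integer(l)       # plen of last taken entry
  ids_t <- vector("list", 2L * l); plen_t <- vector("list", 2L * l)
  for (t in seq_len(l)) {
    tr <- f$trees[[t]]
    rows <- (t - 1L) * depth + seq_len(depth)
    if (!is.null(record_col)) {
      pos[t] <- tr$rank[record_col]
      lcp0r[t] <- depth                   # the entry itself
      lcp0l[t] <- if (pos[t] > 1L) tr$lcp[pos[t] - 1L] else -1L
    } else {
      qk <- qvals[rows]
      pos[t] <- .lex_lower_bound(f, t, qk, rows)
      lcp0r[t] <- if (pos[t] <= n) .lcp2(qk, f$S[rows, tr$ord[pos[t]]], depth) else -1L
      lcp0l[t] <- if (pos[t] > 1L) .lcp2(qk, f$S[rows, tr$ord[pos[t] - 1L]], depth) else -1L
    }
    min_r[t] <- lcp0r[t]; min_l[t] <- lcp0l[t]
  }
  extend <- function(t, side, chunk) {
    tr <- f$trees[[t]]
    if (side == "r") {
      start <- pos[t] + taken_r[t]
      cnt <- min(chunk, n - start + 1L)
      if (cnt <= 0L) return(FALSE)
      sel <- start + seq_len(cnt) - 1L
      seed_val <- if (taken_r[t] == 0L) lcp0r[t] else min_r[t]
      adj <- if (taken_r[t] == 0L) {
        if (cnt > 1L) tr$lcp[sel[-cnt]] else NULL
      } else tr$lcp[sel - 1L]
      plen <- cummin(c(seed_val, adj))
      if (taken_r[t] > 0L) plen <- plen[-1L]
      stopifnot(length(plen) == cnt)
      ids_t[[2L * t - 1L]] <<- c(ids_t[[2L * t - 1L]], f$ids[tr$ord[sel]])
      plen_t[[2L * t - 1L]] <<- c(plen_t[[2L * t - 1L]], plen)
      taken_r[t] <<- taken_r[t] + cnt
      min_r[t] <<- plen[cnt]
    } else {
      start <- pos[t] - taken_l[t] - 1L
      cnt <- min(chunk, start)
      if (cnt <= 0L) return(FALSE)
      sel <- start - seq_len(cnt) + 1L
      seed_val <- if (taken_l[t] == 0L) lcp0l[t] else min_l[t]
      adj <- if (taken_l[t] == 0L) {
        if (cnt > 1L) tr$lcp[sel[-1L]] else NULL
      } else tr$lcp[sel]
      plen <- cummin(c(seed_val, adj))
      if (taken_l[t] > 0L) plen <- plen[-1L]
      stopifnot(length(plen) == cnt)
      ids_t[[2L * t]] <<- c(ids_t[[2L * t]], f$ids[tr$ord[sel]])
      plen_t[[2L * t]] <<- c(plen_t[[2L * t]], plen)
      taken_l[t] <<- taken_l[t] + cnt
      min_l[t] <<- plen[cnt]
    }
    TRUE
  }
  for (t in seq_len(l)) { extend(t, "r", W); extend(t, "l", W) }
  # stopping level: plen of the poolcap-th distinct candidate (0 if fewer)
  level <- function() {
    ids <- unlist(ids_t); plen <- unlist(plen_t)
    o <- order(-plen, ids)
    keep <- !duplicated(ids[o])
    pl <- plen[o][keep]
    if (length(pl) < poolcap) 0L else pl[poolcap]
  }
  repeat {
    L <- level()
    grew <- FALSE
    for (t in seq_len(l)) {
      while (taken_r[t] + pos[t] - 1L < n && min_r[t] >= L && min_r[t] > 0L) {
        if (!extend(t, "r", W)) break
        grew <- TRUE
      }
      while (taken_l[t] < pos[t] - 1L && min_l[t] >= L && min_l[t] > 0L) {
        if (!extend(t, "l", W)) break
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  L <- level()
  ids <- unlist(ids_t); plen <- unlist(plen_t)
  sel <- plen >= L
  unique(ids[sel])
}

# Exact signature-level re-ranking of a candidate pool.
.rerank <- function(f, qvals, cand_ids, k) {
  cols <- match(cand_ids, f$ids[seq_len(f$n)])
  d <- 1 - colMeans(f$S[, cols, drop = FALSE] == qvals)
  o <- order(d, cand_ids)
  take <- seq_len(min(k, length(o)))
  data.frame(id = cand_ids[o[take]], distance = d[o[take]])
}

#' Augmented c-approximate k-NN query against an LSH forest
#'
#' Gathers a candidate pool of up to `k * kc` distinct records by
#' descending-prefix-length matching across all `l` prefix trees (falling
#' back to shallower prefixes down to depth 0, so the result never has
#' fewer than `min(k, available)` entries), then re-ranks the pool by the
#' exact signature-level estimated Jaccard distance and returns the top
#' `k`, ties broken by ascending id.
#'
#' @param f an indexed [lsh_forest()].
#' @param sig query signature, comparable with the forest contents.
#' @param k number of neighbors.
#' @param kc augmentation factor for the candidate pool.
#' @param exclude_self drop the record whose id equals `self_id`.
#' @param self_id id to exclude when `exclude_self = TRUE`.
#' @return `data.frame` with columns `id`, `distance`, sorted by
#'   ascending distance.
#' @export
forest_query <- function(f, sig, k, kc = 10, exclude_self = FALSE, self_id = NULL) {
  if (!f$indexed) mm_stop("not_indexed", "forest must be indexed before querying")
  if (!inherits(sig, "mh_signature"))
    mm_stop("invalid_parameter", "'sig' must be a signature")
  if (sig$flavor != f$flavor || sig$d != f$d || sig$seed != f$sig_seed)
    mm_stop("incompatible_signature", "query signature lineage does not match forest")
  k <- check_count(k, "k")
  kc <- check_count(kc, "kc")
  W <- min(f$n, k * kc)
  pool <- .gather_pool(f, qvals = sig$values, poolcap = k * kc + exclude_self, W = W)
  if (exclude_self) {
    if (is.null(self_id))
      mm_stop("invalid_parameter", "self_id required when exclude_self = TRUE")
    pool <- setdiff(pool, self_id)
  }
  .rerank(f, sig$values, pool, k)
}

#' Save / load an LSH forest
#'
#' Single-file, version-tagged serialization of the forest contents
#' (parameters, ids, signature matrix, indexed flag).
#'
#' @param f an [lsh_forest()].
#' @param path file path.
#' @return `forest_save()` returns `path` invisibly; `forest_load()`
#'   returns the restored forest (re-indexed if it was indexed).
#' @export
forest_save <- function(f, path) {
  snap <- list(version = 1L, d = f$d, l = f$l, flavor = f$flavor,
               sig_seed = f$sig_seed, ids = f$ids[seq_len(f$n)],
               S = f$S[, seq_len(f$n), drop = FALSE], indexed = f$indexed,
               trees = f$trees)
  saveRDS(snap, path, compress = FALSE)
  invisible(path)
}

#' @rdname forest_save
#' @export
forest_load <- function(path) {
  snap <- readRDS(path)
  if (!identical(snap$version, 1L))
    mm_stop("inconsistent_input", "unknown forest file version")
  f <- lsh_forest(snap$d, snap$l)
  f$flavor <- snap$flavor
  f$sig_seed <- snap$sig_seed
  n <- length(snap$ids)
  if (n > 0L) {
    f$S <- snap$S
    f$ids <- snap$ids
    f$n <- n
  }
  if (isTRUE(snap$indexed)) {
    f$trees <- snap$trees
    f$indexed <- TRUE
  }
  f
}
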
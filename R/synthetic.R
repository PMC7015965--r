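#' Generate clustered binary-set data with known ground truth
#'
#' Each of `n_clusters` clusters owns a random core of `core_size`
#' feature indices; cores are mutually disjoint, so the noiseless
#' cross-cluster Jaccard distance is exactly 1.  A record copies its
#' cluster core, drops each core item independently with probability
#' `p_drop`, and adds `Poisson(p_add)` uniform noise features drawn from
#' the non-core remainder of the universe.  Under independent drops the
#' expected within-cluster Jaccard similarity is
#' `(1 - p_drop)^2 / (1 - p_drop^2)` when `p_add = 0`.
#'
#' A record that would end up empty keeps its smallest core item, so
#' encoders never receive an empty set.
#'
#' @param n number of records.
#' @param n_clusters number of clusters (labels are balanced).
#' @param universe size of the feature universe; cores must fit
#'   disjointly (`n_clusters * core_size <= universe`).
#' @param core_size items per cluster core.
#' @param p_drop per-core-item drop probability.
#' @param p_add expected number of uniform noise items per record.
#' @param seed integer RNG seed; output is a pure function of the
#'   arguments.
#' @return list with `sets` (list of item sets) and `labels` (0-based
#'   cluster ids).
#' @export
generate_clustered_sets <- function(n, n_clusters = 5, universe = 4096,
                                    core_size = 128, p_drop = 0.1,
                                    p_add = 10, seed = 42L) {
  n <- check_count(n, "n")
  n_clusters <- check_count(n_clusters, "n_clusters")
  universe <- check_count(universe, "universe")
  core_size <- check_count(core_size, "core_size")
  if (n_clusters > n)
    mm_stop("invalid_parameter", "n_clusters must be <= n")
  if (p_drop < 0 || p_drop > 1)
    mm_stop("invalid_parameter", "p_drop must be in [0, 1]")
  if (p_add < 0)
    mm_stop("invalid_parameter", "p_add must be non-negative")
  if (n_clusters * core_size > universe)
    mm_stop("invalid_parameter",
            "cores cannot be disjoint: n_clusters * core_size > universe")
  with_seed(seed, {
    core_items <- sample.int(universe, n_clusters * core_size) - 1L
    cores <- split(core_items, rep(seq_len(n_clusters), each = core_size))
    noise_pool <- setdiff(seq_len(universe) - 1L, core_items)
    labels <- sort(rep_len(seq_len(n_clusters) - 1L, n))
    sets <- vector("list", n)
    for (i in seq_len(n)) {
      core <- cores[[labels[i] + 1L]]
      keep <- core[stats::runif(core_size) >= p_drop]
      n_noise <- if (p_add > 0) stats::rpois(1, p_add) else 0L
      noise <- if (n_noise > 0L && length(noise_pool) > 0L)
        sample(noise_pool, min(n_noise, length(noise_pool))) else integer(0)
      s <- sort(unique(c(keep, noise)))
      if (length(s) == 0L) s <- min(core)
      sets[[i]] <- s
    }
    list(sets = sets, labels = labels)
  })
}

#' Generate clustered non-negative weighted vectors
#'
#' Cluster centers are sparse non-negative prototypes on mutually
#' disjoint support blocks (hence orthogonal: noiseless cross-cluster
#' generalized Jaccard is 0); records are the center plus Gaussian noise
#' truncated at zero.
#'
#' @param n number of records.
#' @param n_clusters number of clusters.
#' @param dim vector dimensionality (`dim >= n_clusters`).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer RNG seed.
#' @return list with `vectors` (an `n x dim` matrix) and `labels`
#'   (0-based cluster ids).
#' @export
generate_weighted_vectors <- function(n, n_clusters = 5, dim = 64,
                                      noise_sd = 0.1, seed = 42L) {
  n <- check_count(n, "n")
  n_clusters <- check_count(n_clusters, "n_clusters")
  dim <- check_count(dim, "dim")
  if (dim < n_clusters)
    mm_stop("invalid_parameter", "dim must be >= n_clusters")
  if (noise_sd < 0)
    mm_stop("invalid_parameter", "noise_sd must be non-negative")
  with_seed(seed, {
    block <- dim %/% n_clusters
    centers <- matrix(0, n_clusters, dim)
    for (c_ in seq_len(n_clusters)) {
      sup <- (c_ - 1L) * block + seq_len(block)
      centers[c_, sup] <- stats::runif(block, 0.5, 2)
    }
    labels <- sort(rep_len(seq_len(n_clusters) - 1L, n))
    noise <- matrix(stats::rnorm(n * dim, 0, noise_sd), n, dim)
    vectors <- pmax(centers[labels + 1L, , drop = FALSE] + noise, 0)
    # a record must keep at least one positive weight
    zero_rows <- rowSums(vectors) == 0
    if (any(zero_rows)) {
      first_sup <- (labels[zero_rows]) * block + 1L
      vectors[cbind(which(zero_rows), first_sup)] <- 0.5
    }
    list(vectors = vectors, labels = labels)
  })
}

#' Write / read item-set files
#'
#' The token-set exchange format: one record per line, the 0-based
#' feature indices separated by single spaces (an optional first column
#' `id<TAB>` is produced when `ids` is supplied).  Labels are written as
#' a one-column TSV.
#'
#' @param sets list of item sets.
#' @param path output file.
#' @param ids optional explicit record ids.
#' @return `path`, invisibly.
#' @export
write_sets_file <- function(sets, path, ids = NULL) {
  lines <- vapply(sets, function(s) paste(s, collapse = " "), character(1))
  if (!is.null(ids)) lines <- paste(ids, lines, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sets_file
#' @param labels integer labels to store alongside a data set.
#' @export
write_labels_file <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}
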
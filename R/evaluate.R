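#' Hop distances along tree edges
#'
#' Breadth-first topological distances from `source` to every vertex of
#' the spanning forest; vertices in other components are `Inf`.
#'
#' @param forest a `"spanning_forest"`.
#' @param source 0-based source vertex.
#' @return numeric vector of hop counts (length `n`).
#' @export
topological_distances <- function(forest, source) {
  n <- forest$n
  if (length(source) != 1L || source < 0 || source >= n || source != floor(source))
    mm_stop("range_error", "source vertex out of range")
  adj <- .adjacency(forest)
  dist <- rep(Inf, n)
  dist[source + 1L] <- 0
  queue <- source + 1L
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (u in adj[[v]]) {
      if (is.infinite(dist[u + 1L])) {
        dist[u + 1L] <- dist[v] + 1
        queue <- c(queue, u + 1L)
      }
    }
  }
  dist
}

.adjacency <- function(g) {
  adj <- vector("list", g$n)
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$u[i] + 1L]] <- c(adj[[e$u[i] + 1L]], e$v[i])
    adj[[e$v[i] + 1L]] <- c(adj[[e$v[i] + 1L]], e$u[i])
  }
  adj
}

#' Exact nearest neighbor of every record in the original space
#'
#' Argmin over exact Jaccard distance, ties broken by smallest id.
#'
#' @param sets list of item sets.
#' @return integer vector of 0-based nearest-neighbor ids.
#' @export
true_nearest_neighbors <- function(sets) {
  n <- length(sets)
  if (n < 2L) mm_stop("invalid_parameter", "need at least two records")
  d <- jaccard_distance_matrix(sets)
  diag(d) <- Inf
  max.col(-d, ties.method = "first") - 1L
}

#' Locality preservation of an embedding
#'
#' For every record, all other records are ordered by distance in the
#' embedding -- either `"topological"` (hop count on the drawn tree) or
#' `"euclidean"` (distance between layout coordinates) -- with ties
#' broken by ascending id, and the rank position of the record's true
#' nearest neighbor in the original high-dimensional space is reported.
#' A perfectly locality-preserving embedding has every rank equal to 1.
#'
#' @param sets list of item sets (the original space).
#' @param layout an `"mst_layout"` (required for the euclidean metric).
#' @param forest a `"spanning_forest"` (required for the topological
#'   metric).
#' @param metric `"topological"` or `"euclidean"`.
#' @param true_nn optional precomputed [true_nearest_neighbors()] result.
#' @return an object of class `"preservation_report"`: integer `ranks`
#'   (one per record, in `[1, n - 1]`), the `metric`, and a `summary`
#'   list with `mean`, `median` and `fraction_rank1`.
#' @export
nn_preservation <- function(sets, layout = NULL, forest = NULL,
                            metric = c("topological", "euclidean"),
                            true_nn = NULL) {
  metric <- match.arg(metric)
  n <- length(sets)
  if (n < 2L) mm_stop("invalid_parameter", "need at least two records")
  if (is.null(true_nn)) true_nn <- true_nearest_neighbors(sets)
  if (length(true_nn) != n)
    mm_stop("inconsistent_input", "true_nn length does not match sets")
  if (metric == "topological") {
    if (is.null(forest) || forest$n != n)
      mm_stop("inconsistent_input", "forest with matching n required")
  } else {
    if (is.null(layout) || nrow(layout$coordinates) != n)
      mm_stop("inconsistent_input", "layout with matching n required")
  }
  ranks <- integer(n)
  for (i in seq_len(n)) {
    if (metric == "topological") {
      dist <- topological_distances(forest, i - 1L)
    } else {
      xy <- layout$coordinates
      dist <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    }
    nn <- true_nn[i] + 1L
    d_nn <- dist[nn]
    others <- setdiff(seq_len(n), i)
    # rank under (distance, id) ordering; Inf ties also break by id
    before <- sum(dist[others] < d_nn) +
      sum(dist[others] == d_nn & others < nn)
    ranks[i] <- before + 1L
  }
  structure(list(ranks = ranks, metric = metric, true_nn = true_nn,
                 summary = list(mean = mean(ranks),
                                median = stats::median(ranks),
                                fraction_rank1 = mean(ranks == 1L))),
            class = "preservation_report")
}

#' @export
#' @method print preservation_report
print.preservation_report <- function(x, ...) {
  cat(sprintf(paste0("Locality preservation (%s metric): mean rank %.2f, ",
                     "median %.1f, fraction at rank 1: %.3f\n"),
              x$metric, x$summary$mean, x$summary$median,
              x$summary$fraction_rank1))
  invisible(x)
}
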
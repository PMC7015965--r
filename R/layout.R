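#' Layout configuration
#'
#' Parameters of the multilevel spring-electrical layout (phase IV).
#'
#' @param p spacing parameter: the ratio of the repulsive-force scale to
#'   the unit spring length.  Larger values spread vertices further
#'   apart; it is the one knob that should be adjusted with the size of
#'   the input.
#' @param iterations_per_level force iterations at the coarsest level;
#'   halved for each finer level with a floor of 30.
#' @param theta Barnes-Hut opening angle in `(0, 2]`; a quadtree cell of
#'   side `s` at distance `d` is treated as a single point when
#'   `s / d < theta`.  `theta = 0` requests exact pairwise summation.
#' @param coarsest_size stop coarsening once a level has at most this
#'   many vertices.
#' @param seed integer seed; coarsest-level placement and prolongation
#'   jitter derive their streams from it.
#' @return an object of class `"layout_config"`.
#' @export
layout_config <- function(p = 1 / 65, iterations_per_level = 100, theta = 0.9,
                          coarsest_size = 8, seed = 42L) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    mm_stop("invalid_parameter", "p must be a positive number")
  iterations_per_level <- check_count(iterations_per_level, "iterations_per_level")
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 2)
    mm_stop("invalid_parameter", "theta must be in [0, 2]")
  coarsest_size <- check_count(coarsest_size, "coarsest_size", min = 2L)
  structure(list(p = p, iterations_per_level = iterations_per_level,
                 theta = theta, coarsest_size = coarsest_size,
                 seed = as.integer(seed)),
            class = "layout_config")
}

#' Coarsening hierarchy of a spanning forest
#'
#' Builds successively smaller forests by collapsing a maximal matching
#' of tree edges at each level.  Vertices are visited in order of
#' decreasing degree (ties by ascending id) and matched with their
#' unmatched neighbor of smallest id; matched pairs merge into one coarse
#' vertex.  Coarsening stops once a level has at most `coarsest_size`
#' vertices or no edge can be matched.
#'
#' @param forest a `"spanning_forest"` (or any `"neighbor_graph"` that is
#'   a forest).
#' @param coarsest_size target size of the coarsest level.
#' @return list of levels, finest first; each level has `n`, `edges`,
#'   and `map` (0-based coarse vertex id per vertex; `NULL` at the
#'   coarsest level).
#' @export
coarsen_forest <- function(forest, coarsest_size = 8) {
  coarsest_size <- check_count(coarsest_size, "coarsest_size", min = 2L)
  levels <- list()
  n <- forest$n
  edges <- forest$edges
  repeat {
    lev <- list(n = n, edges = edges, map = NULL)
    levels[[length(levels) + 1L]] <- lev
    if (n <= coarsest_size || nrow(edges) == 0L) break
    deg <- tabulate(c(edges$u, edges$v) + 1L, nbins = n)
    adj <- vector("list", n)
    for (i in seq_len(nrow(edges))) {
      adj[[edges$u[i] + 1L]] <- c(adj[[edges$u[i] + 1L]], edges$v[i])
      adj[[edges$v[i] + 1L]] <- c(adj[[edges$v[i] + 1L]], edges$u[i])
    }
    partner <- rep(NA_integer_, n)
    for (v in order(-deg, seq_len(n))) {       # v is 1-based
      if (!is.na(partner[v])) next
      nbr <- adj[[v]]
      nbr <- nbr[is.na(partner[nbr + 1L])]
      if (length(nbr) == 0L) next
      u <- min(nbr)                            # 0-based neighbor
      partner[v] <- u
      partner[u + 1L] <- v - 1L
    }
    if (all(is.na(partner))) break
    rep_of <- pmin(seq_len(n) - 1L, ifelse(is.na(partner), seq_len(n) - 1L, partner))
    reps <- sort(unique(rep_of))
    map <- match(rep_of, reps) - 1L
    mu <- map[edges$u + 1L]; mv <- map[edges$v + 1L]
    keep <- mu != mv
    cu <- pmin(mu[keep], mv[keep]); cv <- pmax(mu[keep], mv[keep])
    cw <- edges$w[keep]
    if (length(cu) > 0L) {
      key <- cu * length(reps) + cv
      o <- order(key, cw)
      first <- !duplicated(key[o])
      cedges <- data.frame(u = cu[o][first], v = cv[o][first], w = cw[o][first])
    } else {
      cedges <- data.frame(u = integer(0), v = integer(0), w = numeric(0))
    }
    levels[[length(levels)]]$map <- map
    n <- length(reps)
    edges <- cedges
  }
  levels
}

# Multilevel layout of one connected component (local 0-based ids).
.layout_component <- function(n, edges, config, comp_tag) {
  if (n == 1L)
    return(list(coords = matrix(0, 1, 2), e_init = 0, e_final = 0))
  levels <- coarsen_forest(list(n = n, edges = edges), config$coarsest_size)
  L <- length(levels)
  emat <- as.matrix(levels[[L]]$edges[, c("u", "v")])
  storage.mode(emat) <- "integer"
  nc <- levels[[L]]$n
  pos <- with_seed(derive_seed(config$seed, paste0("init:", comp_tag)),
                   matrix(stats::runif(nc * 2, 0, sqrt(nc)), ncol = 2))
  iters <- vapply(seq_len(L), function(j)
    max(30L, as.integer(round(config$iterations_per_level / 2^(L - j)))),
    integer(1))
  # coarsest level: exact pairwise forces
  res <- refine_layout_cpp(pos, emat, iters[L], 1.0, 0.9, 0.0, config$p, 1.0)
  pos <- res$coordinates
  e_init <- res$energy_initial; e_final <- res$energy_final
  if (L > 1L) {
    for (j in seq(L - 1L, 1L)) {
      map <- levels[[j]]$map
      jit <- with_seed(derive_seed(config$seed, paste0("prolong:", comp_tag, ":", j)),
                       matrix(stats::runif(levels[[j]]$n * 2, -0.05, 0.05), ncol = 2))
      pos <- pos[map + 1L, , drop = FALSE] + jit
      emat <- as.matrix(levels[[j]]$edges[, c("u", "v")])
      storage.mode(emat) <- "integer"
      # refinement starts near the prolonged equilibrium: a smaller initial
      # step keeps the descent in the same basin instead of re-scrambling it
      res <- refine_layout_cpp(pos, emat, iters[j], 0.25, 0.9, config$theta,
                               config$p, 1.0)
      pos <- res$coordinates
      e_init <- res$energy_initial; e_final <- res$energy_final
    }
  }
  list(coords = pos, e_init = e_init, e_final = e_final)
}

#' Lay out a spanning forest on the plane
#'
#' Phase IV: each connected component is coarsened by edge matchings,
#' its coarsest level is placed at seeded random positions and refined
#' with exact pairwise forces, and each finer level is initialized by
#' prolongation with seeded jitter and refined with spring attraction
#' along tree edges and Barnes-Hut-approximated repulsion.  Components
#' are then packed on a grid (largest first) with margins equal to each
#' component's bounding-box diagonal.  The result is a deterministic
#' function of `(forest, config)`.
#'
#' @param forest a `"spanning_forest"`.
#' @param config a [layout_config()].
#' @return an object of class `"mst_layout"`: `coordinates` (`n x 2`
#'   matrix), `edges` (the drawn tree edges), `config`, and the finest
#'   level's spring-electrical `energy_initial` / `energy_final` summed
#'   over components.
#' @export
layout_forest <- function(forest, config = layout_config()) {
  if (!inherits(forest, "spanning_forest"))
    mm_stop("invalid_parameter", "'forest' must be a spanning_forest")
  if (!inherits(config, "layout_config"))
    mm_stop("invalid_parameter", "'config' must be a layout_config()")
  n <- forest$n
  if (n == 0L) mm_stop("empty_input", "empty forest")
  comp <- forest$components
  ncomp <- max(comp) + 1L
  coords <- matrix(NA_real_, n, 2)
  e_init <- 0; e_final <- 0
  boxes <- vector("list", ncomp)
  for (c_ in seq_len(ncomp) - 1L) {
    members <- which(comp == c_) - 1L          # 0-based original ids
    sel <- forest$edges$u %in% members
    le <- forest$edges[sel, , drop = FALSE]
    lu <- match(le$u, members) - 1L
    lv <- match(le$v, members) - 1L
    res <- .layout_component(length(members),
                             data.frame(u = lu, v = lv, w = le$w),
                             config, c_)
    coords[members + 1L, ] <- res$coords
    e_init <- e_init + res$e_init
    e_final <- e_final + res$e_final
    boxes[[c_ + 1L]] <- c(range(res$coords[, 1]), range(res$coords[, 2]),
                          length(members))
  }
  if (ncomp > 1L) {
    sizes <- vapply(boxes, function(b) b[5], numeric(1))
    widths <- vapply(boxes, function(b) b[2] - b[1], numeric(1))
    heights <- vapply(boxes, function(b) b[4] - b[3], numeric(1))
    diags <- sqrt(widths^2 + heights^2)
    pitch <- max(pmax(widths, heights) + diags) + 1
    ordc <- order(-sizes, seq_along(sizes))
    ncols <- ceiling(sqrt(ncomp))
    for (slot in seq_along(ordc)) {
      c_ <- ordc[slot] - 1L
      b <- boxes[[c_ + 1L]]
      cxy <- c(mean(b[1:2]), mean(b[3:4]))
      target <- c(((slot - 1L) %% ncols) * pitch,
                  -((slot - 1L) %/% ncols) * pitch)
      members <- which(comp == c_)
      coords[members, 1] <- coords[members, 1] - cxy[1] + target[1]
      coords[members, 2] <- coords[members, 2] - cxy[2] + target[2]
    }
  }
  structure(list(coordinates = coords, edges = forest$edges, config = config,
                 energy_initial = e_init, energy_final = e_final),
            class = "mst_layout")
}

#' @export
#' @method print mst_layout
print.mst_layout <- function(x, ...) {
  cat(sprintf("Tree layout: %d vertices, %d drawn edges\n",
              nrow(x$coordinates), nrow(x$edges)))
  invisible(x)
}

#' Rescale a layout to a target extent
#'
#' Affine rescaling so the longer side of the bounding box equals
#' `target_extent`, with the lower-left bounding-box corner at the
#' origin; aspect ratio (hence all distance ratios) is preserved.
#'
#' @param r an `"mst_layout"`.
#' @param target_extent positive target for the longer bounding-box side.
#' @return the rescaled `"mst_layout"`.
#' @export
scale_layout <- function(r, target_extent) {
  if (!inherits(r, "mst_layout"))
    mm_stop("invalid_parameter", "'r' must be an mst_layout")
  if (!is.numeric(target_extent) || target_extent <= 0)
    mm_stop("invalid_parameter", "target_extent must be positive")
  xy <- r$coordinates
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  ext <- max(rngx[2] - rngx[1], rngy[2] - rngy[1])
  if (ext <= 0) mm_stop("degenerate_layout", "all points coincide")
  xy[, 1] <- (xy[, 1] - rngx[1]) * (target_extent / ext)
  xy[, 2] <- (xy[, 2] - rngy[1]) * (target_extent / ext)
  r$coordinates <- xy
  r
}

#' @export
plot.mst_layout <- function(x, col = "grey40", pch = 16, cex = 0.5, ...) {
  xy <- x$coordinates
  graphics::plot(xy, asp = 1, xlab = "x", ylab = "y", type = "n", ...)
  e <- x$edges
  if (nrow(e) > 0L)
    graphics::segments(xy[e$u + 1L, 1], xy[e$u + 1L, 2],
                       xy[e$v + 1L, 1], xy[e$v + 1L, 2], col = "grey70")
  graphics::points(xy, col = col, pch = pch, cex = cex)
  invisible(x)
}
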
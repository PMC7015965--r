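#' Fit a tree map of a high-dimensional data set
#'
#' Runs the four-phase pipeline: (I) MinHash (binary sets) or consistent
#' weighted sampling (non-negative vectors) sketches are indexed in an
#' LSH forest of `l` prefix trees; (II) a c-approximate k-nearest-
#' neighbor graph is built with the augmented forest query, its edges
#' weighted by estimated Jaccard distance; (III) a minimum spanning
#' forest is extracted with Kruskal's algorithm; (IV) the forest is laid
#' out on the plane by a deterministic multilevel spring-electrical
#' model.  A precomputed undirected weighted graph (a
#' `"neighbor_graph"` or an edge-list `data.frame` with columns
#' `u, v, w`) skips phases I-II.
#'
#' All randomness derives from `seed`; two runs with identical input and
#' parameters produce identical results.
#'
#' @param x a list of item sets, a non-negative numeric matrix (one
#'   record per row), a `"neighbor_graph"`, or an edge-list `data.frame`.
#' @param d number of hash functions per signature.
#' @param l number of LSH prefix trees (`d` must be divisible by `l`).
#' @param k neighbors per record in phase II.
#' @param kc augmentation factor of the candidate pool.
#' @param p layout spacing parameter (see [layout_config()]).
#' @param iterations layout force iterations at the coarsest level.
#' @param theta Barnes-Hut opening angle.
#' @param coarsest_size coarsening stop size.
#' @param seed master integer seed.
#' @return an object of class `"mstmap"` with components `coordinates`
#'   (`n x 2`), `layout`, `forest`, `graph`, `config`, `timings`,
#'   `counts`, `n`, and `input_kind`.
#' @examples
#' syn <- generate_clustered_sets(60, n_clusters = 3, universe = 512,
#'                                core_size = 32, seed = 7)
#' fit <- mstmap(syn$sets, d = 64, l = 8, k = 5, kc = 5, seed = 7)
#' print(fit)
#' @export
mstmap <- function(x, d = 128, l = 8, k = 10, kc = 10, p = 1 / 65,
                   iterations = 100, theta = 0.9, coarsest_size = 8,
                   seed = 42L) {
  lay_cfg <- layout_config(p = p, iterations_per_level = iterations,
                           theta = theta, coarsest_size = coarsest_size,
                           seed = derive_seed(seed, "layout"))
  timings <- c(I = 0, II = 0, III = 0, IV = 0)
  if (inherits(x, "neighbor_graph") ||
      (is.data.frame(x) && all(c("u", "v", "w") %in% names(x)))) {
    input_kind <- "edge_list"
    graph <- if (inherits(x, "neighbor_graph")) x
             else graph_from_edge_list(max(x$u, x$v) + 1, x$u, x$v, x$w)
    forest_idx <- NULL
  } else {
    t0 <- proc.time()[["elapsed"]]
    forest_idx <- lsh_forest(d, l)
    if (is.matrix(x)) {
      input_kind <- "weighted"
      fam <- weighted_hash_family(d, ncol(x), seed = derive_seed(seed, "hash"))
      forest_add(forest_idx, weighted_minhash_signatures(x, fam))
    } else if (is.list(x)) {
      input_kind <- "sets"
      fam <- hash_family(d, seed = derive_seed(seed, "hash"))
      forest_add(forest_idx, minhash_signatures(x, fam))
    } else {
      mm_stop("invalid_parameter",
              "'x' must be a list of sets, a matrix, or a graph/edge list")
    }
    forest_index(forest_idx)
    timings["I"] <- proc.time()[["elapsed"]] - t0
    t0 <- proc.time()[["elapsed"]]
    graph <- build_knn_graph(forest_idx, k = k, kc = kc)
    timings["II"] <- proc.time()[["elapsed"]] - t0
  }
  t0 <- proc.time()[["elapsed"]]
  forest <- kruskal_forest(graph)
  timings["III"] <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  layout <- layout_forest(forest, lay_cfg)
  timings["IV"] <- proc.time()[["elapsed"]] - t0
  structure(list(
    coordinates = layout$coordinates,
    layout = layout,
    forest = forest,
    graph = graph,
    index = forest_idx,
    config = list(d = d, l = l, k = k, kc = kc, p = p,
                  iterations = iterations, theta = theta,
                  coarsest_size = coarsest_size, seed = as.integer(seed)),
    timings = timings,
    counts = list(n = graph$n, edges = nrow(graph$edges),
                  tree_edges = nrow(forest$edges),
                  components = max(forest$components) + 1L),
    n = graph$n,
    input_kind = input_kind
  ), class = "mstmap")
}

#' @export
#' @method print mstmap
print.mstmap <- function(x, ...) {
  cat(sprintf("Tree map of %d records (%s input)\n", x$n, x$input_kind))
  cat(sprintf("  k-NN graph edges: %d;  tree edges: %d;  components: %d\n",
              x$counts$edges, x$counts$tree_edges, x$counts$components))
  invisible(x)
}

#' @export
#' @method summary mstmap
summary.mstmap <- function(object, ...) {
  cat(sprintf("Tree map of %d records (%s input)\n", object$n, object$input_kind))
  cfg <- object$config
  cat(sprintf("  parameters: d = %d, l = %d, k = %d, kc = %d, p = %.4g, seed = %d\n",
              cfg$d, cfg$l, cfg$k, cfg$kc, cfg$p, cfg$seed))
  cat(sprintf("  k-NN graph: %d edges, mean Jaccard distance %.3f\n",
              object$counts$edges, mean(object$graph$edges$w)))
  cat(sprintf("  spanning forest: %d edges, %d component(s), total weight %.3f\n",
              object$counts$tree_edges, object$counts$components,
              sum(object$forest$edges$w)))
  cat(sprintf("  layout energy: %.4g (initial) -> %.4g (final)\n",
              object$layout$energy_initial, object$layout$energy_final))
  cat(sprintf("  phase seconds: I %.2f, II %.2f, III %.2f, IV %.2f\n",
              object$timings[["I"]], object$timings[["II"]],
              object$timings[["III"]], object$timings[["IV"]]))
  invisible(object)
}

#' @export
#' @rdname mstmap
#' @param labels optional per-record group labels used to color points.
#' @param ... passed on to the underlying plot.
plot.mstmap <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) "grey40"
         else grDevices::hcl.colors(length(unique(labels)),
                                    "Dark 3")[as.integer(factor(labels))]
  plot(x$layout, col = col, ...)
  invisible(x)
}

.md5_of <- function(path_or_obj) {
  if (is.character(path_or_obj) && length(path_or_obj) == 1L &&
      file.exists(path_or_obj)) return(unname(tools::md5sum(path_or_obj)))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(path_or_obj, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline and write its outputs
#'
#' Drives [mstmap()] from a file or in-memory input and writes
#' coordinates TSV, tree-edge TSV, GraphML and a JSON run manifest under
#' `prefix`.  On failure, partial outputs are removed.  The coordinate
#' and edge files are byte-identical across reruns with identical input
#' and configuration.
#'
#' @param input a file path (interpreted per `kind`) or an in-memory
#'   object accepted by [mstmap()].
#' @param out output path prefix; files `<out>_coords.tsv`,
#'   `<out>_tree.tsv`, `<out>.graphml`, `<out>_manifest.json`
#'   (and optionally `<out>.png`) are created.  (Named `out`, not
#'   `prefix`, so the layout parameter `p` in `...` can never be
#'   partially matched to it.)
#' @param kind input kind: `"sets"`, `"tokens"`, `"weighted"` or
#'   `"edge_list"`; auto-detected for in-memory input.
#' @param write_plot also write a static PNG of the layout.
#' @param ... pipeline parameters passed to [mstmap()].
#' @return invisibly, a list with the fitted `"mstmap"` object, the
#'   output `files`, and the run `manifest`.
#' @export
run_pipeline <- function(input, out, kind = NULL, write_plot = FALSE, ...) {
  t_all <- proc.time()[["elapsed"]]
  if (is.character(input) && length(input) == 1L) {
    if (is.null(kind))
      mm_stop("invalid_parameter", "'kind' is required for file input")
    x <- switch(kind,
                sets = read_sets_file(input, "index_set")$sets,
                tokens = read_sets_file(input, "tokens")$sets,
                weighted = read_matrix_file(input),
                edge_list = read_edge_list(input),
                mm_stop("invalid_parameter", paste0("unknown input kind: ", kind)))
    checksum <- .md5_of(input)
  } else {
    x <- input
    checksum <- .md5_of(input)
    if (is.null(kind)) {
      kind <- if (inherits(x, "neighbor_graph") || is.data.frame(x)) "edge_list"
              else if (is.matrix(x)) "weighted" else "sets"
    }
  }
  files <- c(coords = paste0(out, "_coords.tsv"),
             tree = paste0(out, "_tree.tsv"),
             graphml = paste0(out, ".graphml"),
             manifest = paste0(out, "_manifest.json"))
  if (write_plot) files <- c(files, plot = paste0(out, ".png"))
  ok <- FALSE
  on.exit(if (!ok) unlink(files))
  fit <- mstmap(x, ...)
  write_coordinates(fit$layout, files[["coords"]])
  write_edges(fit$forest, files[["tree"]])
  write_graphml(fit$forest, files[["graphml"]], layout = fit$layout)
  if (write_plot) {
    grDevices::png(files[["plot"]], width = 1200, height = 1200, res = 150)
    plot(fit)
    grDevices::dev.off()
  }
  manifest <- list(
    package = "mstmap",
    version = as.character(utils::packageVersion("mstmap")),
    config = fit$config,
    seed = fit$config$seed,
    input = list(kind = kind, checksum = checksum, n = fit$n),
    phases = list(
      I = list(seconds = unname(fit$timings[["I"]]), n = fit$n),
      II = list(seconds = unname(fit$timings[["II"]]),
                edges = fit$counts$edges),
      III = list(seconds = unname(fit$timings[["III"]]),
                 tree_edges = fit$counts$tree_edges,
                 components = fit$counts$components),
      IV = list(seconds = unname(fit$timings[["IV"]]))),
    total_seconds = proc.time()[["elapsed"]] - t_all)
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  ok <- TRUE
  invisible(list(fit = fit, files = files, manifest = manifest))
}

#' Write layout outputs for an existing fit
#'
#' @param fit an `"mstmap"` object.
#' @param prefix output path prefix.
#' @param plot also write a static PNG.
#' @return named character vector of written files, invisibly.
#' @export
write_outputs <- function(fit, prefix, plot = FALSE) {
  files <- c(coords = paste0(prefix, "_coords.tsv"),
             tree = paste0(prefix, "_tree.tsv"),
             graphml = paste0(prefix, ".graphml"))
  write_coordinates(fit$layout, files[["coords"]])
  write_edges(fit$forest, files[["tree"]])
  write_graphml(fit$forest, files[["graphml"]], layout = fit$layout)
  if (plot) {
    files <- c(files, plot = paste0(prefix, ".png"))
    grDevices::png(files[["plot"]], width = 1200, height = 1200, res = 150)
    plot(fit)
    grDevices::dev.off()
  }
  invisible(files)
}
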
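#' Read item sets from a delimited text file
#'
#' Two dialects: `"index_set"` -- one record per line, 0-based feature
#' indices separated by spaces, with an optional leading `id<TAB>`
#' column; `"tokens"` -- one document per line, whitespace-separated
#' tokens, for which a corpus-wide vocabulary is built and each document
#' becomes the set of vocabulary indices of its distinct tokens.  Blank
#' lines are skipped; ids default to 0-based line numbers.
#'
#' @param path input file.
#' @param dialect `"index_set"` or `"tokens"`.
#' @return list with `ids`, `sets`, and (tokens dialect) `vocabulary`.
#' @export
read_sets_file <- function(path, dialect = c("index_set", "tokens")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) mm_stop("io", paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  lines <- lines[keep]
  if (dialect == "tokens") {
    toks <- strsplit(trimws(lines), "\\s+")
    vocab_terms <- sort(unique(unlist(toks)))
    vocabulary <- stats::setNames(seq_along(vocab_terms) - 1L, vocab_terms)
    sets <- lapply(toks, set_from_tokens, vocabulary = vocabulary)
    return(list(ids = seq_along(sets) - 1L, sets = sets,
                vocabulary = vocabulary))
  }
  ids <- numeric(length(lines))
  sets <- vector("list", length(lines))
  has_id <- grepl("\t", lines, fixed = TRUE)
  for (i in seq_along(lines)) {
    body <- lines[i]
    if (has_id[i]) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      idv <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(idv))
        mm_stop("parse", sprintf("line %d: malformed id field", keep[i]))
      ids[i] <- idv
      body <- paste(parts[-1], collapse = " ")
    } else {
      ids[i] <- i - 1
    }
    items <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
    if (anyNA(items) || any(items < 0) || any(items != floor(items)))
      mm_stop("parse", sprintf("line %d: expected non-negative integer indices",
                               keep[i]))
    sets[[i]] <- sort(unique(items))
  }
  if (any(has_id) && anyDuplicated(ids))
    mm_stop("duplicate_id", "duplicate explicit record id in sets file")
  list(ids = ids, sets = sets)
}

#' Read a delimited numeric matrix (one record per row)
#'
#' Field separator (comma, tab or whitespace) and an optional header row
#' are auto-detected.
#'
#' @param path input file.
#' @return numeric matrix.
#' @export
read_matrix_file <- function(path) {
  if (!file.exists(path)) mm_stop("io", paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  probe <- strsplit(first, if (sep == ",") "," else "\\s+")[[1]]
  header <- anyNA(suppressWarnings(as.numeric(probe[nzchar(probe)])))
  m <- as.matrix(utils::read.table(path, header = header, sep = sep))
  storage.mode(m) <- "double"
  if (anyNA(m)) mm_stop("parse", "non-numeric entries in matrix file")
  m
}

#' Read an edge list TSV (columns u, v, w; 0-based vertex ids)
#'
#' @param path input file.
#' @param n vertex count; defaults to `max(u, v) + 1`.
#' @return a `"neighbor_graph"` via [graph_from_edge_list()].
#' @export
read_edge_list <- function(path, n = NULL) {
  if (!file.exists(path)) mm_stop("io", paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  probe <- strsplit(first, "\\s+")[[1]]
  header <- anyNA(suppressWarnings(as.numeric(probe[nzchar(probe)])))
  e <- utils::read.table(path, header = header)
  if (ncol(e) < 3L) mm_stop("parse", "edge list needs columns u, v, w")
  names(e)[1:3] <- c("u", "v", "w")
  if (is.null(n)) n <- max(e$u, e$v) + 1
  graph_from_edge_list(n, e$u, e$v, e$w)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write / read layout coordinates as TSV
#'
#' Full-precision (`%.17g`) tab-separated `id, x, y`; a round trip
#' reproduces the coordinates exactly to double precision.
#'
#' @param layout an `"mst_layout"` (or a two-column coordinate matrix).
#' @param path output file.
#' @param ids optional record ids; default 0-based row numbers.
#' @return `path` invisibly; `read_coordinates()` returns a data.frame
#'   with columns `id`, `x`, `y`.
#' @export
write_coordinates <- function(layout, path, ids = NULL) {
  xy <- if (inherits(layout, "mst_layout")) layout$coordinates else layout
  if (is.null(ids)) ids <- seq_len(nrow(xy)) - 1L
  lines <- c("id\tx\ty",
             paste(ids, .fmt(xy[, 1]), .fmt(xy[, 2]), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_coordinates
#' @export
read_coordinates <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("numeric", "numeric", "numeric"),
                    col.names = c("id", "x", "y"))
}

#' Write a weighted edge table as TSV (columns u, v, w)
#'
#' @param g a `"neighbor_graph"`, `"spanning_forest"` or edge data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(g, path) {
  e <- if (is.data.frame(g)) g else g$edges
  lines <- c("u\tv\tw", paste(e$u, e$v, .fmt(e$w), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

.xml_num <- function(x) sub("e([+-])0(\\d\\d)$", "e\\1\\2", .fmt(x))

#' Export a graph or forest to GraphML
#'
#' Writes an undirected GraphML document with edge weights and,
#' when a layout is given, `x`/`y` vertex attributes.
#'
#' @param g a `"neighbor_graph"` or `"spanning_forest"`.
#' @param path output file.
#' @param layout optional `"mst_layout"` supplying coordinates.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path, layout = NULL) {
  n <- g$n
  e <- g$edges
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns"',
    '         xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"',
    '         xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>')
  if (!is.null(layout)) {
    head <- c(head,
              '  <key id="x" for="node" attr.name="x" attr.type="double"/>',
              '  <key id="y" for="node" attr.name="y" attr.type="double"/>')
  }
  head <- c(head, '  <graph id="G" edgedefault="undirected">')
  if (is.null(layout)) {
    nodes <- sprintf('    <node id="n%d"/>', seq_len(n) - 1L)
  } else {
    xy <- layout$coordinates
    nodes <- sprintf(paste0('    <node id="n%d"><data key="x">%s</data>',
                            '<data key="y">%s</data></node>'),
                     seq_len(n) - 1L, .xml_num(xy[, 1]), .xml_num(xy[, 2]))
  }
  edges <- sprintf('    <edge source="n%d" target="n%d"><data key="w">%s</data></edge>',
                   e$u, e$v, .xml_num(e$w))
  writeLines(c(head, nodes, edges, "  </graph>", "</graphml>"), path)
  invisible(path)
}
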
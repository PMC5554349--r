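#' Construct a network object
#'
#' The central container of the package: a set of nodes and a set of
#' undirected-by-topology edges with display attributes.  All layout,
#' clustering and statistics code treats the graph as undirected; the
#' \code{directed} edge flag is carried through to the renderer, which draws
#' arrowheads, but never influences computation.
#'
#' Duplicate edges between the same unordered node pair are collapsed and
#' their weights summed, so repeated evidence for an interaction accumulates.
#' Self-loops are rejected with a warning (nothing downstream consumes them);
#' the number dropped is recorded in the load report
#' (\code{attr(g, "load_report")}).
#'
#' @param edges data.frame with at least columns \code{source} and
#'   \code{target} (character ids); optional \code{weight} (positive),
#'   \code{directed} (0/1), \code{color} (hex string), \code{pattern}.
#' @param nodes optional data.frame with column \code{id} plus any of
#'   \code{name}, \code{color}, \code{texture}, \code{size},
#'   \code{magnitude}, \code{cluster}, \code{layer}, \code{x}, \code{y},
#'   \code{z}.  Nodes appearing only in \code{edges} are added with defaults.
#' @return an object of class \code{nv_graph}
#' @export
nv_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && !all(c("source", "target") %in% names(edges)))
    stop("edge table needs 'source' and 'target' columns")
  if (nrow(edges) == 0 && !"source" %in% names(edges)) {
    edges$source <- character(0); edges$target <- character(0)
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight)) stop("non-numeric edge weight")
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  if (is.null(edges$directed)) edges$directed <- rep(FALSE, nrow(edges))
  if (is.character(edges$directed))   # "0"/"1" from table files
    edges$directed <- suppressWarnings(as.integer(edges$directed)) != 0
  edges$directed <- as.logical(edges$directed)
  edges$directed[is.na(edges$directed)] <- FALSE
  if (is.null(edges$color)) edges$color <- rep(NA_character_, nrow(edges))
  if (is.null(edges$pattern)) edges$pattern <- rep(NA_character_, nrow(edges))

  report <- list(self_loops = 0L, duplicates = 0L, warnings = character())

  loops <- edges$source == edges$target
  if (any(loops)) {
    report$self_loops <- sum(loops)
    report$warnings <- c(report$warnings,
                         sprintf("%d self-loop(s) dropped", sum(loops)))
    warning(sprintf("%d self-loop(s) dropped", sum(loops)), call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }

  # collapse duplicate undirected edges, summing weight
  if (nrow(edges) > 0) {
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target), sep = "\r")
    if (anyDuplicated(key)) {
      report$duplicates <- sum(duplicated(key))
      w <- tapply(edges$weight, key, sum)
      keep <- !duplicated(key)
      edges <- edges[keep, , drop = FALSE]
      edges$weight <- as.numeric(w[paste(pmin(edges$source, edges$target),
                                         pmax(edges$source, edges$target),
                                         sep = "\r")])
    }
    rownames(edges) <- NULL
  }

  ids <- unique(c(if (!is.null(nodes)) as.character(nodes$id),
                  edges$source, edges$target))
  nd <- data.frame(id = ids, stringsAsFactors = FALSE)
  defaults <- list(name = NA_character_, color = NA_character_,
                   texture = NA_character_, size = 1, magnitude = NA_real_,
                   cluster = NA_integer_, layer = NA_integer_,
                   x = NA_real_, y = NA_real_, z = NA_real_)
  for (f in names(defaults)) nd[[f]] <- rep(defaults[[f]], length(ids))
  if (!is.null(nodes) && nrow(nodes) > 0) {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (!"id" %in% names(nodes)) stop("node table needs an 'id' column")
    if (anyDuplicated(nodes$id)) stop("duplicate node ids in node table")
    idx <- match(as.character(nodes$id), nd$id)
    for (f in intersect(names(defaults), names(nodes)))
      nd[[f]][idx] <- nodes[[f]]
  }
  nd$name <- ifelse(is.na(nd$name), nd$id, nd$name)
  nd$size <- as.numeric(nd$size)
  nd$size[is.na(nd$size)] <- 1
  if (any(nd$size <= 0)) stop("node sizes must be positive")
  xyz <- c(nd$x, nd$y, nd$z)
  if (any(!is.na(xyz) & !is.finite(xyz))) stop("node coordinates must be finite")

  missing_ep <- setdiff(c(edges$source, edges$target), nd$id)
  if (length(missing_ep) > 0) stop("edge endpoint(s) not in node set: ",
                                   paste(missing_ep, collapse = ", "))

  g <- structure(list(nodes = nd, edges = edges), class = "nv_graph")
  attr(g, "load_report") <- report
  g
}

#' @export
print.nv_graph <- function(x, ...) {
  cat(sprintf("<nv_graph> %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Number of nodes
#' @param g an \code{nv_graph}
#' @export
n_nodes <- function(g) nrow(g$nodes)

#' Number of edges
#' @param g an \code{nv_graph}
#' @export
n_edges <- function(g) nrow(g$edges)

#' Node ids in storage order
#' @param g an \code{nv_graph}
#' @export
node_ids <- function(g) g$nodes$id

#' Per-node degree (number of incident edges, direction ignored)
#' @param g an \code{nv_graph}
#' @return named integer vector over all nodes
#' @export
node_degrees <- function(g) {
  d <- table(factor(c(g$edges$source, g$edges$target), levels = g$nodes$id))
  stats::setNames(as.integer(d), g$nodes$id)
}

#' Convert to an igraph object (undirected, weighted)
#' @param g an \code{nv_graph}
#' @keywords internal
as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = g$edges[, c("source", "target", "weight")],
    directed = FALSE,
    vertices = data.frame(name = g$nodes$id, stringsAsFactors = FALSE))
}

#' Connected components, largest first
#'
#' Components are the unit at which several statistics apply their
#' minimum-size rule and at which spectral bisection operates.
#'
#' @param g an \code{nv_graph}
#' @return list of character vectors of node ids; ordered by decreasing
#'   size, ties broken by the smallest contained id
#' @export
connected_components <- function(g) {
  if (n_nodes(g) == 0) return(list())
  comp <- igraph::components(as_igraph(g))
  sets <- split(g$nodes$id, comp$membership[g$nodes$id])
  sets <- lapply(sets, as.character)
  smallest <- vapply(sets, function(s) min(s), character(1))
  ord <- order(-lengths(sets), smallest)
  unname(sets[ord])
}

# ---- file I/O ------------------------------------------------------------

.read_table_file <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(NULL)
  con <- textConnection(lines)
  on.exit(close(con))
  utils::read.table(con, sep = sep, header = .has_header(lines[1], sep),
                    quote = "\"", stringsAsFactors = FALSE,
                    comment.char = "", check.names = FALSE,
                    colClasses = "character")
}

.has_header <- function(first_line, sep) {
  f <- strsplit(first_line, sep, fixed = TRUE)[[1]]
  any(tolower(f) %in% c("source", "target", "id", "weight"))
}

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a network from a delimited table
#'
#' The native dialect: TAB-separated for \code{.tsv}/\code{.txt}, comma for
#' \code{.csv}; optional header.  First two columns are source and target
#' ids; further columns (by header name, or positionally
#' \code{weight, directed, color, pattern}) are optional.
#'
#' @param path file path
#' @param node_table optional path of a companion node attribute table
#'   (columns \code{id}, then any of \code{name,color,texture,size,magnitude,
#'   cluster,layer,x,y,z})
#' @return an \code{nv_graph}
#' @export
read_network_table <- function(path, node_table = NULL) {
  sep <- .sep_for(path)
  tab <- .read_table_file(path, sep)
  if (is.null(tab)) return(nv_graph())
  if (ncol(tab) < 2) {
    bad <- which(!grepl(sep, readLines(path, warn = FALSE), fixed = TRUE))[1]
    stop(sprintf("parse error at line %d of %s: fewer than 2 columns",
                 if (is.na(bad)) 1L else bad, path))
  }
  cn <- names(tab)
  if (!"source" %in% cn) {
    std <- c("source", "target", "weight", "directed", "color", "pattern")
    names(tab) <- std[seq_len(min(ncol(tab), length(std)))]
  } else {
    names(tab)[names(tab) == "edge_color"] <- "color"
    names(tab)[names(tab) == "edge_pattern"] <- "pattern"
  }
  if ("weight" %in% names(tab)) {
    w <- suppressWarnings(as.numeric(tab$weight))
    if (anyNA(w)) {
      bad <- which(is.na(w))[1]
      stop(sprintf("parse error near line %d of %s: non-numeric weight '%s'",
                   bad, path, tab$weight[bad]))
    }
    tab$weight <- w
  }
  nodes <- if (!is.null(node_table)) read_node_table(node_table) else NULL
  nv_graph(tab, nodes)
}

#' Read a companion node attribute table
#' @param path TSV/CSV with header; first column \code{id}
#' @return data.frame suitable for the \code{nodes} argument of
#'   \code{\link{nv_graph}}
#' @export
read_node_table <- function(path) {
  tab <- .read_table_file(path, .sep_for(path))
  if (is.null(tab)) return(NULL)
  if (!"id" %in% names(tab)) names(tab)[1] <- "id"
  names(tab)[names(tab) == "node_color"] <- "color"
  for (f in intersect(c("size", "magnitude", "x", "y", "z"), names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[f]]))
    bad <- which(is.na(v) & !is.na(tab[[f]]) & nzchar(tab[[f]]))
    if (length(bad) > 0)
      stop(sprintf("parse error near line %d of %s: non-numeric %s '%s'",
                   bad[1], path, f, tab[[f]][bad[1]]))
    tab[[f]] <- v
  }
  tab
}

#' Read pinned 3D coordinates (id, x, y, z)
#'
#' Used for physically constrained networks, e.g. residue-contact graphs
#' where each node is an alpha-carbon position.
#'
#' @param path TSV with columns id, x, y, z (header optional)
#' @param graph optional \code{nv_graph}; ids absent from it are reported in
#'   the \code{unknown_ids} attribute rather than silently dropped
#' @return data.frame(id, x, y, z); attribute \code{unknown_ids}
#' @export
read_coordinates <- function(path, graph = NULL) {
  tab <- .read_table_file(path, .sep_for(path))
  if (is.null(tab))
    return(structure(data.frame(id = character(), x = numeric(),
                                y = numeric(), z = numeric()),
                     unknown_ids = character()))
  names(tab) <- c("id", "x", "y", "z")[seq_len(min(4, ncol(tab)))]
  for (f in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tab[[f]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("parse error near line %d of %s: bad coordinate '%s'",
                   bad[1], path, tab[[f]][bad[1]]))
    tab[[f]] <- v
  }
  unknown <- character()
  if (!is.null(graph)) {
    unknown <- setdiff(tab$id, node_ids(graph))
    if (length(unknown) > 0)
      warning("coordinate ids not in graph: ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(tab[, c("id", "x", "y", "z")], unknown_ids = unknown)
}

#' Write a graph in the native TSV dialect
#' @param g an \code{nv_graph}
#' @param path output edge-table path
#' @param node_table optional path for the companion node table
#' @export
write_network_table <- function(g, path, node_table = NULL) {
  e <- g$edges
  out <- data.frame(source = e$source, target = e$target,
                    weight = e$weight,
                    directed = as.integer(e$directed),
                    edge_color = ifelse(is.na(e$color), "", e$color),
                    edge_pattern = ifelse(is.na(e$pattern), "", e$pattern),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(node_table)) {
    nd <- g$nodes
    names(nd)[names(nd) == "color"] <- "node_color"
    nd[] <- lapply(nd, function(v) ifelse(is.na(v), "", as.character(v)))
    utils::write.table(nd, node_table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.read_sif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) == 1)  # isolated node
      return(data.frame(source = f[1], target = NA_character_,
                        pattern = NA_character_, stringsAsFactors = FALSE))
    if (length(f) < 3)
      stop(sprintf("parse error at line %d of %s: SIF needs id type id", i, path))
    # one source, interaction type, >= 1 targets
    data.frame(source = f[1], target = f[-(1:2)], pattern = f[2],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  iso <- tab$source[is.na(tab$target)]
  tab <- tab[!is.na(tab$target), , drop = FALSE]
  nodes <- if (length(iso) > 0) data.frame(id = iso) else NULL
  nv_graph(tab, nodes)
}

.write_sif <- function(g, path) {
  e <- g$edges
  has_attrs <- any(!is.na(e$color)) || any(e$weight != 1)
  if (has_attrs)
    warning("SIF cannot carry edge weights/colors; attributes dropped",
            call. = FALSE)
  type <- ifelse(is.na(e$pattern), "pp", e$pattern)
  lines <- paste(e$source, type, e$target, sep = "\t")
  iso <- setdiff(g$nodes$id, c(e$source, e$target))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Convert between network file formats
#'
#' Supported: the native \code{tsv}/\code{csv} edge tables and Cytoscape-style
#' \code{sif}.  A tsv -> sif -> tsv round trip preserves the node set and edge
#' set; attributes SIF cannot carry (weights, colors) are dropped with a
#' warning.
#'
#' @param in_path,out_path input and output file paths
#' @param in_format,out_format one of \code{"sif"}, \code{"csv"}, \code{"tsv"}
#' @export
convert_format <- function(in_path, in_format, out_path, out_format) {
  fmts <- c("sif", "csv", "tsv")
  if (!in_format %in% fmts || !out_format %in% fmts)
    stop("unknown format; valid: ", paste(fmts, collapse = ", "))
  g <- if (in_format == "sif") .read_sif(in_path) else
    read_network_table(in_path)
  if (out_format == "sif") {
    .write_sif(g, out_path)
  } else if (out_format == "tsv") {
    write_network_table(g, out_path)
  } else {
    e <- g$edges
    out <- data.frame(source = e$source, target = e$target, weight = e$weight)
    utils::write.table(out, out_path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out_path)
}

#' Export a layout (and optionally the graph) for external viewers
#' @param layout an \code{nv_layout}
#' @param path output path; \code{.json} gives a
#'   \code{{nodes, edges, positions}} document, anything else the
#'   \code{id,x,y,z} TSV
#' @param graph graph to embed in the JSON form
#' @export
write_layout <- function(layout, path, graph = NULL) {
  pos <- unclass(layout)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- list(
      nodes = if (is.null(graph)) data.frame(id = rownames(pos)) else
        graph$nodes,
      edges = if (is.null(graph)) NULL else graph$edges,
      positions = stats::setNames(
        lapply(seq_len(nrow(pos)), function(i) unname(pos[i, ])),
        rownames(pos)))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    out <- data.frame(id = rownames(pos), x = pos[, 1], y = pos[, 2],
                      z = pos[, 3])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
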
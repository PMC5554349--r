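# Network topology statistics: eight per-node/network metrics, rank-ordered
# tables, distribution series, and a report writer.  Weighted shortest paths
# use edge weight as length throughout.  Several metrics apply the
# minimum-component rule: only nodes in components with more than 3 nodes
# (size >= 4) are evaluated; excluded nodes are reported blank (NA), not 0.

.component_sizes <- function(g) {
  comps <- connected_components(g)
  sz <- stats::setNames(rep(lengths(comps), lengths(comps)), unlist(comps))
  sz[g$nodes$id]
}

.distance_matrix <- function(g) {
  if (n_nodes(g) == 0) return(matrix(0, 0, 0))
  igraph::distances(as_igraph(g), weights = g$edges$weight)
}

#' Degree distribution
#' @param g an \code{nv_graph}
#' @return list with \code{degrees} (named vector) and \code{histogram}
#'   (data.frame degree, count)
#' @export
degree_distribution <- function(g) {
  deg <- node_degrees(g)
  hist <- if (length(deg) == 0)
    data.frame(degree = integer(), count = integer())
  else {
    tab <- table(deg)
    data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
  }
  list(degrees = deg, histogram = hist)
}

#' Neighborhood connectivity
#'
#' Mean degree of a node's neighbors; undefined (NA) for isolated nodes.
#' The series averages the metric over nodes of equal degree, the usual
#' diagnostic for degree assortativity and modular structure.
#'
#' @param g an \code{nv_graph}
#' @return list with \code{per_node} (named vector, NA for isolated nodes)
#'   and \code{series} (data.frame degree, mean_connectivity)
#' @export
neighborhood_connectivity <- function(g) {
  deg <- node_degrees(g)
  ids <- g$nodes$id
  nbr_sum <- stats::setNames(rep(0, length(ids)), ids)
  for (i in seq_len(n_edges(g))) {
    s <- g$edges$source[i]; t <- g$edges$target[i]
    nbr_sum[s] <- nbr_sum[s] + deg[t]
    nbr_sum[t] <- nbr_sum[t] + deg[s]
  }
  per <- ifelse(deg > 0, nbr_sum / deg, NA_real_)
  eval_ok <- !is.na(per)
  series <- if (!any(eval_ok))
    data.frame(degree = integer(), mean_connectivity = numeric())
  else {
    agg <- tapply(per[eval_ok], deg[eval_ok], mean)
    data.frame(degree = as.integer(names(agg)),
               mean_connectivity = as.numeric(agg))
  }
  list(per_node = per, series = series)
}

#' Local clustering coefficients
#'
#' \code{C_i = 2 e_i / (k_i (k_i - 1))}: the fraction of possible edges
#' among a node's neighbors that exist, 0 (no interconnection) to 1
#' (perfect interconnection).  Nodes with fewer than 2 neighbors score 0.
#' Nodes in components of 3 or fewer nodes are excluded (NA) from both the
#' per-node values and the network average.
#'
#' @param g an \code{nv_graph}
#' @return list with \code{per_node} (named, NA where excluded) and
#'   \code{average}
#' @export
clustering_coefficients <- function(g) {
  n <- n_nodes(g)
  if (n == 0) return(list(per_node = numeric(0), average = NA_real_))
  ig <- as_igraph(g)
  cc <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  cc <- stats::setNames(cc, g$nodes$id)
  cc[.component_sizes(g) <= 3] <- NA_real_
  avg <- if (all(is.na(cc))) NA_real_ else mean(cc, na.rm = TRUE)
  list(per_node = cc, average = avg)
}

#' Closeness centrality
#'
#' Reciprocal of the summed weighted shortest-path distances from a node to
#' every other node of its own component.  Nodes in components of 3 or
#' fewer nodes are excluded (NA).  The network closeness is the mean over
#' evaluated nodes.  \code{normalized = TRUE} multiplies by (component
#' size - 1) for cross-graph comparability.
#'
#' @param g an \code{nv_graph}
#' @param normalized logical
#' @return list with \code{per_node} and \code{network}
#' @export
closeness_centrality <- function(g, normalized = FALSE) {
  n <- n_nodes(g)
  if (n == 0) return(list(per_node = numeric(0), network = NA_real_))
  D <- .distance_matrix(g)
  D[!is.finite(D)] <- NA
  sums <- rowSums(D, na.rm = TRUE)
  cl <- ifelse(sums > 0, 1 / sums, NA_real_)
  csz <- .component_sizes(g)
  cl[csz <= 3] <- NA_real_
  if (normalized) cl <- cl * (csz - 1)
  cl <- stats::setNames(as.numeric(cl), g$nodes$id)
  net <- if (all(is.na(cl))) NA_real_ else mean(cl, na.rm = TRUE)
  list(per_node = cl, network = net)
}

#' Node betweenness centrality
#'
#' Number of shortest paths between all node pairs that pass through each
#' node, with fractional credit when several shortest paths tie.  Weighted
#' shortest paths use weight as length.
#'
#' @param g an \code{nv_graph}
#' @return named numeric vector
#' @export
betweenness_centrality <- function(g) {
  if (n_nodes(g) == 0) return(numeric(0))
  b <- igraph::betweenness(as_igraph(g), directed = FALSE,
                           weights = g$edges$weight)
  stats::setNames(as.numeric(b), g$nodes$id)
}

# all-pairs shortest-path counts sigma[s, t] via dynamic programming over
# nodes in increasing distance from each source
.path_counts <- function(g, D) {
  n <- n_nodes(g)
  ids <- g$nodes$id
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n_edges(g))) {
    adj[g$edges$source[i], g$edges$target[i]] <- g$edges$weight[i]
    adj[g$edges$target[i], g$edges$source[i]] <- g$edges$weight[i]
  }
  sigma <- matrix(0, n, n, dimnames = list(ids, ids))
  tol <- 1e-9
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(adj[, t] > 0 &
                    abs(D[s, ] + adj[, t] - D[s, t]) < tol)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  sigma
}

#' Diameter, mean path length and shortest-path load
#'
#' Diameter is the largest finite pairwise distance (unconnected pairs are
#' ignored; blank for an edgeless graph); the average is over connected
#' pairs only.  The per-node load counts the shortest paths (all of them,
#' not fractional shares) passing strictly through each node.  The load is
#' skipped (NA) above \code{load_limit} nodes, where the cubic pair scan
#' becomes the dominant cost of a report.
#'
#' @param g an \code{nv_graph}
#' @param load_limit node-count cap for the exact load computation
#' @return list with \code{diameter}, \code{average_path_length},
#'   \code{load} (named vector)
#' @export
path_metrics <- function(g, load_limit = 2000) {
  n <- n_nodes(g)
  if (n == 0)
    return(list(diameter = NA_real_, average_path_length = NA_real_,
                load = numeric(0)))
  D <- .distance_matrix(g)
  finite <- is.finite(D) & upper.tri(D)
  diam <- if (any(finite)) max(D[finite]) else NA_real_
  apl <- if (any(finite)) mean(D[finite]) else NA_real_
  load <- stats::setNames(rep(NA_real_, n), g$nodes$id)
  if (n <= load_limit && n_edges(g) > 0) {
    sigma <- .path_counts(g, D)
    tol <- 1e-9
    for (v in seq_len(n)) {
      through <- 0
      for (s in seq_len(n - 1)) {
        if (s == v) next
        ts <- (s + 1):n
        ts <- ts[ts != v & is.finite(D[s, ts])]
        hit <- ts[abs(D[s, v] + D[v, ts] - D[s, ts]) < tol]
        if (length(hit) > 0)
          through <- through + sum(sigma[s, v] * sigma[v, hit])
      }
      load[v] <- through
    }
  }
  list(diameter = diam, average_path_length = apl, load = load)
}

#' Shared nearest neighbors
#'
#' \code{SNN(u, v) = |N(u) intersect N(v)|} over direct neighbors; only
#' pairs sharing at least one neighbor are reported.
#'
#' @param g an \code{nv_graph}
#' @return data.frame(u, v, snn), u < v
#' @export
shared_nearest_neighbors <- function(g) {
  n <- n_nodes(g)
  if (n == 0 || n_edges(g) == 0)
    return(data.frame(u = character(), v = character(), snn = integer()))
  ids <- g$nodes$id
  A <- Matrix::sparseMatrix(
    i = c(match(g$edges$source, ids), match(g$edges$target, ids)),
    j = c(match(g$edges$target, ids), match(g$edges$source, ids)),
    x = 1, dims = c(n, n))
  S <- A %*% A
  S <- Matrix::triu(S, k = 1)
  idx <- Matrix::which(S >= 1, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(u = character(), v = character(), snn = integer()))
  out <- data.frame(u = ids[idx[, 1]], v = ids[idx[, 2]],
                    snn = as.integer(S[idx]), stringsAsFactors = FALSE)
  out[order(out$u, out$v), , drop = FALSE]
}

.metric_names <- c("degree", "neighborhood_connectivity", "clustering",
                   "closeness", "betweenness", "load", "snn_max")

#' Full topology statistics report
#'
#' Computes all per-node metrics, rank-orders the node table by the chosen
#' metric (excluded nodes last), and assembles the network-level summary
#' and distribution series.  \code{write_report} turns the object into CSV
#' tables and PNG distribution plots.
#'
#' @param g an \code{nv_graph}
#' @param rank_by metric to order the table by; one of degree,
#'   neighborhood_connectivity, clustering, closeness, betweenness, load,
#'   snn_max
#' @return object of class \code{nv_stats_report}: list(per_node, network,
#'   distributions)
#' @export
generate_report <- function(g, rank_by = "degree") {
  if (!rank_by %in% .metric_names)
    stop("unknown metric '", rank_by, "'; valid: ",
         paste(.metric_names, collapse = ", "))
  dd <- degree_distribution(g)
  nc <- neighborhood_connectivity(g)
  cc <- clustering_coefficients(g)
  cl <- closeness_centrality(g)
  bt <- betweenness_centrality(g)
  pm <- path_metrics(g)
  snn <- shared_nearest_neighbors(g)
  snn_max <- stats::setNames(rep(0, n_nodes(g)), g$nodes$id)
  for (i in seq_len(nrow(snn))) {
    snn_max[snn$u[i]] <- max(snn_max[snn$u[i]], snn$snn[i])
    snn_max[snn$v[i]] <- max(snn_max[snn$v[i]], snn$snn[i])
  }
  per <- data.frame(
    id = g$nodes$id,
    degree = as.numeric(dd$degrees),
    neighborhood_connectivity = as.numeric(nc$per_node),
    clustering = as.numeric(cc$per_node),
    closeness = as.numeric(cl$per_node),
    betweenness = as.numeric(bt),
    load = as.numeric(pm$load),
    snn_max = as.numeric(snn_max),
    stringsAsFactors = FALSE)
  key <- per[[rank_by]]
  per <- per[order(is.na(key), -ifelse(is.na(key), 0, key), per$id), ,
             drop = FALSE]
  rownames(per) <- NULL
  structure(list(
    per_node = per,
    network = list(n = n_nodes(g), m = n_edges(g),
                   diameter = pm$diameter,
                   average_clustering = cc$average,
                   network_closeness = cl$network,
                   average_path_length = pm$average_path_length),
    distributions = list(degree_histogram = dd$histogram,
                         connectivity_vs_degree = nc$series),
    snn_pairs = snn,
    rank_by = rank_by), class = "nv_stats_report")
}

#' @export
print.nv_stats_report <- function(x, ...) {
  cat(sprintf("<nv_stats_report> n=%d m=%d diameter=%s ranked by %s\n",
              x$network$n, x$network$m,
              format(x$network$diameter), x$rank_by))
  invisible(x)
}

#' Write a statistics report to disk
#'
#' One CSV per table (per-node metrics, network summary, SNN pairs, both
#' distribution series) and one PNG bar/line chart per distribution,
#' rendered by the package's deterministic software rasterizer on a white
#' background.
#'
#' @param report an \code{nv_stats_report}
#' @param out_dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
  }
  wr(report$per_node, "per_node.csv")
  wr(data.frame(metric = names(report$network),
                value = unlist(lapply(report$network, function(v)
                  if (is.na(v)) NA else v))), "network.csv")
  wr(report$snn_pairs, "snn_pairs.csv")
  wr(report$distributions$degree_histogram, "degree_histogram.csv")
  wr(report$distributions$connectivity_vs_degree,
     "connectivity_vs_degree.csv")
  dh <- report$distributions$degree_histogram
  p1 <- file.path(out_dir, "degree_histogram.png")
  .plot_bars(dh$degree, dh$count, "degree", p1)
  files <- c(files, p1)
  cs <- report$distributions$connectivity_vs_degree
  p2 <- file.path(out_dir, "connectivity_vs_degree.png")
  .plot_bars(cs$degree, cs$mean_connectivity, "neighbor degree", p2)
  files <- c(files, p2)
  invisible(files)
}
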
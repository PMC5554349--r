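# Seeded synthetic network generators: every algorithm in the package gets a
# test surface without external downloads.  All generators are deterministic
# per seed and return validated nv_graph objects.

.ids_for <- function(n, prefix = "n") sprintf("%s%03d", prefix, seq_len(n))

#' Classic small graphs
#'
#' Paths, stars, cycles, cliques and the barbell (two cliques joined by one
#' bridge edge) used throughout the tests and examples.
#'
#' @param n number of nodes (for the barbell: nodes per clique)
#' @param prefix node-id prefix
#' @name classic_graphs
NULL

#' @rdname classic_graphs
#' @export
make_path <- function(n, prefix = "n") {
  ids <- .ids_for(n, prefix)
  e <- if (n > 1) data.frame(source = ids[-n], target = ids[-1]) else NULL
  nv_graph(e, data.frame(id = ids))
}

#' @rdname classic_graphs
#' @export
make_star <- function(n, prefix = "n") {
  ids <- .ids_for(n, prefix)
  e <- if (n > 1) data.frame(source = ids[1], target = ids[-1]) else NULL
  nv_graph(e, data.frame(id = ids))
}

#' @rdname classic_graphs
#' @export
make_cycle <- function(n, prefix = "n") {
  ids <- .ids_for(n, prefix)
  e <- data.frame(source = ids, target = ids[c(2:n, 1)])
  nv_graph(e, data.frame(id = ids))
}

#' @rdname classic_graphs
#' @export
make_clique <- function(n, prefix = "n") {
  ids <- .ids_for(n, prefix)
  pr <- t(utils::combn(ids, 2))
  nv_graph(data.frame(source = pr[, 1], target = pr[, 2]),
           data.frame(id = ids))
}

#' @rdname classic_graphs
#' @param bridge_weight weight of the bridge edge
#' @export
make_barbell <- function(n = 3, bridge_weight = 1) {
  a <- make_clique(n, "a"); b <- make_clique(n, "b")
  e <- rbind(a$edges[, c("source", "target", "weight")],
             b$edges[, c("source", "target", "weight")],
             data.frame(source = sprintf("a%03d", n), target = "b001",
                        weight = bridge_weight))
  nv_graph(e, data.frame(id = c(a$nodes$id, b$nodes$id)))
}

#' Planted-partition (modular) graph
#'
#' k communities of equal size; within-community node pairs are connected
#' with probability \code{p_in}, cross-community pairs with \code{p_out}.
#' The planted labels are returned for cluster-recovery tests.
#'
#' @param k number of communities
#' @param size nodes per community
#' @param p_in,p_out edge probabilities, \code{0 <= p_out < p_in <= 1}
#' @param seed RNG seed
#' @return list(graph, partition) with partition an \code{nv_partition}
#' @export
make_modular <- function(k, size, p_in, p_out, seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1")
  n <- k * size
  ids <- .ids_for(n)
  lab <- rep(seq_len(k) - 1L, each = size)
  with_seed(seed, {
    pr <- t(utils::combn(seq_len(n), 2))
    p <- ifelse(lab[pr[, 1]] == lab[pr[, 2]], p_in, p_out)
    keep <- stats::runif(nrow(pr)) < p
    e <- data.frame(source = ids[pr[keep, 1]], target = ids[pr[keep, 2]])
    g <- nv_graph(if (nrow(e) > 0) e else NULL,
                  data.frame(id = ids, cluster = lab))
    list(graph = g, partition = nv_partition(stats::setNames(lab, ids)))
  })
}

#' Scale-free graph by preferential attachment
#'
#' Growth model for hub-dominated interactomes: each new node attaches to
#' \code{m_per} distinct existing nodes with probability proportional to
#' their current degree.  Connected by construction;
#' \code{m = m_per * (n - m_per)} edges.
#'
#' @param n total nodes (\code{n >= m_per >= 1})
#' @param m_per edges added per new node
#' @param seed RNG seed
#' @export
make_scale_free <- function(n, m_per = 1, seed = 1) {
  stopifnot(n >= m_per, m_per >= 1)
  ids <- .ids_for(n)
  with_seed(seed, {
    deg <- rep(0, n)
    src <- integer(0); tgt <- integer(0)
    for (v in if (n > m_per) (m_per + 1):n else integer(0)) {
      existing <- seq_len(v - 1)
      w <- deg[existing] + 1   # +1 smoothing so isolated seeds are reachable
      pick <- sample(existing, m_per, prob = w)
      src <- c(src, rep(v, m_per)); tgt <- c(tgt, pick)
      deg[pick] <- deg[pick] + 1; deg[v] <- deg[v] + m_per
    }
    nv_graph(data.frame(source = ids[src], target = ids[tgt]),
             data.frame(id = ids))
  })
}

#' Layered (multi-type) graph
#'
#' Emulates multi-level data such as gene/disease/drug networks: nodes carry
#' a \code{layer} attribute; within-layer and cross-layer pairs are
#' connected with separate densities.  Directly usable as semantic-layout
#' input.
#'
#' @param sizes integer vector of layer sizes
#' @param p_within,p_between edge probabilities in [0, 1]
#' @param seed RNG seed
#' @return list(graph, layers) with layers a named node -> layer-index map
#' @export
make_layered <- function(sizes, p_within = 0.3, p_between = 0.1, seed = 1) {
  stopifnot(all(c(p_within, p_between) >= 0), all(c(p_within, p_between) <= 1))
  n <- sum(sizes)
  ids <- .ids_for(n)
  lab <- rep(seq_along(sizes) - 1L, sizes)
  with_seed(seed, {
    e <- NULL
    if (n > 1) {
      pr <- t(utils::combn(seq_len(n), 2))
      p <- ifelse(lab[pr[, 1]] == lab[pr[, 2]], p_within, p_between)
      keep <- stats::runif(nrow(pr)) < p
      if (any(keep))
        e <- data.frame(source = ids[pr[keep, 1]], target = ids[pr[keep, 2]])
    }
    g <- nv_graph(e, data.frame(id = ids, layer = lab))
    list(graph = g, layers = stats::setNames(lab, ids))
  })
}

#' Coordinate-pinned correlation graph
#'
#' Emulates physically constrained networks (e.g. residue-contact maps):
#' points are laid along a coiled 3D tube, a distance-decaying synthetic
#' correlation matrix is built (\code{exp(-d/correlation_length)} plus
#' seeded noise), and the top-K correlated pairs become edges.  The true
#' coordinates are returned for pinned-layout and bundling tests.
#'
#' @param n number of points
#' @param correlation_length spatial decay length of the correlation
#' @param K number of edges (top correlations), \code{K <= choose(n, 2)}
#' @param seed RNG seed
#' @return list(graph, coordinates) with coordinates a data.frame(id, x, y, z)
#' @export
make_coordinate_pinned <- function(n, correlation_length = 2, K = 3 * n,
                                   seed = 1) {
  stopifnot(K >= 1, K <= choose(n, 2))
  ids <- .ids_for(n)
  with_seed(seed, {
    t <- seq(0, 4 * pi, length.out = n)
    pos <- cbind(x = 3 * cos(t) + stats::rnorm(n, sd = 0.2),
                 y = 3 * sin(t) + stats::rnorm(n, sd = 0.2),
                 z = t + stats::rnorm(n, sd = 0.2))
    d <- as.matrix(stats::dist(pos))
    corr <- exp(-d / correlation_length) +
      matrix(stats::rnorm(n * n, sd = 0.01), n, n)
    corr <- (corr + t(corr)) / 2
    pr <- which(upper.tri(corr), arr.ind = TRUE)
    ord <- order(-corr[pr])
    top <- pr[ord[seq_len(K)], , drop = FALSE]
    g <- nv_graph(data.frame(source = ids[top[, 1]], target = ids[top[, 2]],
                             weight = pmax(corr[top], 1e-6)),
                  data.frame(id = ids, x = pos[, 1], y = pos[, 2],
                             z = pos[, 3]))
    list(graph = g,
         coordinates = data.frame(id = ids, x = pos[, 1], y = pos[, 2],
                                  z = pos[, 3]))
  })
}

#' Write a fixture to the native TSV dialect
#'
#' Generators used from the command line go through the real I/O path: the
#' graph is written as an edge table plus node table.
#'
#' @param family one of modular, scale_free, layered, coordinate_pinned,
#'   barbell, path, star, cycle, clique
#' @param out_prefix path prefix; writes \code{<prefix>_edges.tsv} and
#'   \code{<prefix>_nodes.tsv}
#' @param seed RNG seed
#' @param ... family-specific parameters
#' @return the generated \code{nv_graph}, invisibly
#' @export
write_fixture <- function(family, out_prefix, seed = 1, ...) {
  args <- list(...)
  g <- switch(family,
    modular = do.call(make_modular, c(args, list(seed = seed)))$graph,
    scale_free = do.call(make_scale_free, c(args, list(seed = seed))),
    layered = do.call(make_layered, c(args, list(seed = seed)))$graph,
    coordinate_pinned =
      do.call(make_coordinate_pinned, c(args, list(seed = seed)))$graph,
    barbell = do.call(make_barbell, args),
    path = do.call(make_path, args),
    star = do.call(make_star, args),
    cycle = do.call(make_cycle, args),
    clique = do.call(make_clique, args),
    stop("unknown fixture family '", family, "'"))
  write_network_table(g, paste0(out_prefix, "_edges.tsv"),
                      paste0(out_prefix, "_nodes.tsv"))
  invisible(g)
}
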
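# Graph clustering: budgeted edge-betweenness sweeps, Markov clustering and
# leading-eigenvector modularity, plus the modularity score itself.

#' Construct a partition object
#' @param membership named vector node id -> cluster label; labels are
#'   relabelled to contiguous integers 0..k-1 in order of first appearance
#' @export
nv_partition <- function(membership) {
  lab <- match(membership, unique(membership)) - 1L
  structure(list(membership = stats::setNames(lab, names(membership)),
                 k = length(unique(lab))), class = "nv_partition")
}

#' @export
print.nv_partition <- function(x, ...) {
  cat(sprintf("<nv_partition> %d nodes in %d clusters\n",
              length(x$membership), x$k))
  invisible(x)
}

.component_partition <- function(g) {
  comps <- connected_components(g)
  mem <- stats::setNames(rep(seq_along(comps) - 1L, lengths(comps)),
                         unlist(comps))
  nv_partition(mem[g$nodes$id])
}

#' Modularity Q of a partition
#'
#' \code{Q = sum_c (e_c/m - (d_c/2m)^2)} with the weighted generalization:
#' \code{e_c} is the weight of intra-cluster edges, \code{d_c} the summed
#' (weighted) degree of the cluster, \code{m} the total edge weight.  Q
#' compares in-cluster edge mass against a degree-preserving random
#' expectation; a single all-in-one cluster scores exactly 0.
#'
#' @param g an \code{nv_graph} with at least one edge
#' @param partition an \code{nv_partition} (or named membership vector)
#'   covering all nodes
#' @return scalar in [-0.5, 1)
#' @export
modularity_score <- function(g, partition) {
  if (n_edges(g) == 0) stop("modularity is undefined for an edgeless graph")
  mem <- if (inherits(partition, "nv_partition")) partition$membership
  else partition
  if (!all(g$nodes$id %in% names(mem))) stop("partition does not cover V")
  m <- sum(g$edges$weight)
  cs <- mem[g$edges$source]; ct <- mem[g$edges$target]
  e_c <- tapply(g$edges$weight[cs == ct], cs[cs == ct], sum)
  str <- tapply(c(g$edges$weight, g$edges$weight),
                c(cs, ct), sum)  # weighted degree per cluster
  q <- sum(e_c) / m - sum((str / (2 * m))^2)
  unname(q)
}

#' Edge betweenness
#'
#' The number of shortest paths between node pairs that run through each
#' edge (fractional credit shared over tied shortest paths).  Edge weights
#' are treated as lengths; \code{weights = "none"} ignores them and
#' \code{weights = "similarity"} uses 1/weight as length, for inputs where a
#' heavier edge means a stronger (shorter) connection.
#'
#' @param g an \code{nv_graph}
#' @param weights \code{"length"} (default), \code{"none"}, or
#'   \code{"similarity"}
#' @return data.frame(source, target, eb)
#' @export
edge_betweenness <- function(g, weights = c("length", "none", "similarity")) {
  weights <- match.arg(weights)
  ig <- as_igraph(g)
  w <- switch(weights, length = g$edges$weight, none = NULL,
              similarity = 1 / g$edges$weight)
  eb <- igraph::edge_betweenness(ig, directed = FALSE, weights = w)
  data.frame(source = g$edges$source, target = g$edges$target, eb = eb,
             stringsAsFactors = FALSE)
}

#' Girvan-Newman edge-betweenness clustering
#'
#' Repeatedly removes the edge with the highest edge-betweenness value,
#' recomputing after each removal, with two stopping/safety rules: the sweep
#' is budgeted at \code{ceiling(removal_fraction * m)} removals (default 0.2
#' of the edges), and any removal that would leave a single-node cluster is
#' skipped.  The returned best partition is the connected-component
#' partition with the highest modularity seen anywhere in the sweep
#' (including before any removal).
#'
#' @param g an \code{nv_graph} with at least one edge
#' @param removal_fraction fraction of edges to remove, in [0, 1]
#' @param weights passed to \code{\link{edge_betweenness}}
#' @return list with \code{removed_edges} (data.frame source, target, eb),
#'   \code{best_partition} (\code{nv_partition}) and \code{best_modularity}
#' @export
cluster_girvan_newman <- function(g, removal_fraction = 0.2,
                                  weights = "length") {
  if (n_edges(g) < 1) stop("need at least one edge")
  if (removal_fraction < 0 || removal_fraction > 1)
    stop("removal_fraction must be in [0, 1]")
  budget <- ceiling(removal_fraction * n_edges(g))
  cur <- g
  best_p <- .component_partition(g)
  best_q <- modularity_score(g, best_p)
  removed <- data.frame(source = character(), target = character(),
                        eb = numeric(), stringsAsFactors = FALSE)
  while (nrow(removed) < budget && n_edges(cur) > 0) {
    eb <- edge_betweenness(cur, weights)
    deg <- node_degrees(cur)
    ord <- order(-eb$eb, eb$source, eb$target)
    pick <- NA_integer_
    for (i in ord) {  # singleton protection: skip edges with a degree-1 end
      if (deg[eb$source[i]] > 1 && deg[eb$target[i]] > 1) { pick <- i; break }
    }
    if (is.na(pick)) break
    removed <- rbind(removed, eb[pick, , drop = FALSE])
    keep <- !(cur$edges$source == eb$source[pick] &
              cur$edges$target == eb$target[pick])
    cur <- nv_graph(cur$edges[keep, , drop = FALSE], cur$nodes)
    p <- .component_partition(cur)
    q <- modularity_score(g, p)   # scored on the original graph
    if (q > best_q + 1e-12) { best_q <- q; best_p <- p }
  }
  rownames(removed) <- NULL
  list(removed_edges = removed, best_partition = best_p,
       best_modularity = best_q)
}

#' Markov clustering (MCL) parameters
#' @param inflation entrywise power applied between expansions (> 1;
#'   higher values give more, smaller clusters)
#' @param expansion matrix power simulating random-walk steps
#' @param prune_threshold entries below this are dropped after inflation
#' @param max_iterations,convergence_tol iteration control
#' @export
mcl_params <- function(inflation = 2, expansion = 2, prune_threshold = 1e-5,
                       max_iterations = 200, convergence_tol = 1e-6) {
  stopifnot(inflation > 1, expansion >= 2)
  structure(list(inflation = inflation, expansion = expansion,
                 prune_threshold = prune_threshold,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol), class = "mcl_params")
}

#' Markov clustering
#'
#' Simulates random-walk flow on the network: the column-stochastic
#' transition matrix is alternately expanded (matrix power) and inflated
#' (entrywise power followed by column renormalization, which sharpens flow
#' inside densely connected regions) until the matrix stops changing.
#' Weight-1 self-loops are added before iteration, the usual regularization
#' that guarantees convergence.  Clusters are read from the connected
#' structure of the converged flow matrix.
#'
#' @param g an \code{nv_graph}
#' @param params an \code{\link{mcl_params}} object
#' @return an \code{nv_partition}; attribute \code{converged} is FALSE with
#'   a warning if \code{max_iterations} was hit
#' @export
cluster_mcl <- function(g, params = mcl_params()) {
  n <- n_nodes(g)
  if (n == 0) return(nv_partition(stats::setNames(integer(0), character(0))))
  ids <- g$nodes$id
  i <- c(match(g$edges$source, ids), match(g$edges$target, ids), seq_len(n))
  j <- c(match(g$edges$target, ids), match(g$edges$source, ids), seq_len(n))
  w <- c(g$edges$weight, g$edges$weight, rep(1, n))
  M <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  norm_cols <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- norm_cols(M)
  converged <- FALSE
  col_dev <- max(abs(Matrix::colSums(M) - 1))
  for (it in seq_len(params$max_iterations)) {
    Mexp <- M
    for (p in seq_len(params$expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp
    Minf@x <- Minf@x^params$inflation
    Minf <- Matrix::drop0(Minf, tol = params$prune_threshold)
    Minf <- norm_cols(Minf)
    col_dev <- max(col_dev, max(abs(Matrix::colSums(Minf) - 1)))
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within max_iterations", call. = FALSE)
  S <- (M + Matrix::t(M)) > params$prune_threshold
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(S, mode = "undirected"))
  p <- nv_partition(stats::setNames(comp$membership, ids))
  attr(p, "converged") <- converged
  attr(p, "col_dev") <- col_dev   # worst column-sum deviation from 1
  p
}

# modularity matrix product B x restricted to a node subset (implicit, so the
# dense matrix is never formed for large groups):
#   (B x)_i = sum_j A_ij x_j - k_i (k . x)/(2m) - x_i * selfterm_i
.bsub_mult <- function(A, k, m2, self, x) {
  drop(A %*% x) - k * sum(k * x) / m2 - self * x
}

#' Leading-eigenvector modularity clustering
#'
#' Recursive spectral bisection on the (weighted) modularity matrix
#' \code{B = A - k k' / 2m}: each group is split by the sign of the leading
#' eigenvector of its restricted modularity matrix, the split kept only if
#' it raises Q; groups whose leading eigenvalue is non-positive or whose
#' split does not improve Q are indivisible and terminate the recursion.
#'
#' @param g an \code{nv_graph} with at least one edge
#' @return an \code{nv_partition}
#' @export
cluster_leading_eigenvector <- function(g) {
  if (n_edges(g) < 1) stop("need at least one edge")
  n <- n_nodes(g)
  ids <- g$nodes$id
  A <- Matrix::sparseMatrix(
    i = c(match(g$edges$source, ids), match(g$edges$target, ids)),
    j = c(match(g$edges$target, ids), match(g$edges$source, ids)),
    x = rep(g$edges$weight, 2), dims = c(n, n))
  k <- Matrix::rowSums(A)
  m2 <- sum(k)
  mem <- rep(0L, n)
  next_label <- 1L
  queue <- list(seq_len(n))
  current_q <- function() modularity_score(g, stats::setNames(mem, ids))
  while (length(queue) > 0) {
    grp <- queue[[1]]; queue <- queue[-1]
    if (length(grp) < 2) next
    Ag <- A[grp, grp, drop = FALSE]
    kg <- k[grp]
    self <- drop(Ag %*% rep(1, length(grp))) - kg * sum(kg) / m2
    v <- .leading_eigvec(Ag, kg, m2, self)
    if (is.null(v)) next
    split <- v > 0
    if (all(split) || !any(split)) next
    old_q <- current_q()
    old_lab <- mem[grp]
    mem[grp[split]] <- next_label
    new_q <- current_q()
    if (new_q > old_q + 1e-10) {
      queue <- c(queue, list(grp[split], grp[!split]))
      next_label <- next_label + 1L
    } else {
      mem[grp] <- old_lab
    }
  }
  nv_partition(stats::setNames(mem, ids))
}

# leading eigenvector of the restricted modularity matrix; dense eigen for
# small groups, shifted power iteration above that.  NULL when the leading
# eigenvalue is non-positive (indivisible group).
.leading_eigvec <- function(Ag, kg, m2, self) {
  ng <- length(kg)
  if (ng <= 400) {
    B <- as.matrix(Ag) - outer(kg, kg) / m2
    diag(B) <- diag(B) - self
    es <- eigen(B, symmetric = TRUE)
    if (es$values[1] <= 1e-12) return(NULL)
    return(es$vectors[, 1])
  }
  shift <- max(abs(kg)) * sum(abs(kg)) / m2 + max(Matrix::rowSums(abs(Ag))) +
    max(abs(self)) + 1
  x <- sin(seq_len(ng)); x <- x / sqrt(sum(x^2))
  for (it in seq_len(10000)) {
    y <- .bsub_mult(Ag, kg, m2, self, x) + shift * x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < 1e-12) { x <- y; break }
    x <- y
  }
  lam <- sum(x * .bsub_mult(Ag, kg, m2, self, x))
  if (lam <= 1e-12) return(NULL)
  x
}
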
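# Independent brute-force oracles used to validate shortest-path statistics,
# spectral bisection and the lin-log energy.  Everything here enumerates or
# uses dense linear algebra and never calls the code paths under test.

# adjacency (weight-as-length) matrix in node order
oracle_adj <- function(g) {
  ids <- node_ids(g)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n_edges(g))) {
    A[g$edges$source[i], g$edges$target[i]] <- g$edges$weight[i]
    A[g$edges$target[i], g$edges$source[i]] <- g$edges$weight[i]
  }
  A
}

# enumerate every simple path between two nodes by depth-first search;
# returns list of paths (vectors of node indices)
oracle_all_paths <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  walk <- function(v, visited, trail) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- trail
      return()
    }
    for (u in seq_len(n)) {
      if (A[v, u] > 0 && !visited[u]) {
        vv <- visited; vv[u] <- TRUE
        walk(u, vv, c(trail, u))
      }
    }
  }
  vis <- rep(FALSE, n); vis[s] <- TRUE
  walk(s, vis, s)
  paths
}

path_len <- function(A, p) {
  if (length(p) < 2) return(0)
  sum(A[cbind(p[-length(p)], p[-1])])
}

# all shortest-path quantities from exhaustive path enumeration
oracle_shortest_paths <- function(g) {
  A <- oracle_adj(g)
  ids <- node_ids(g)
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  node_bw <- stats::setNames(rep(0, n), ids)
  node_load <- stats::setNames(rep(0, n), ids)
  edge_bw <- list()
  ekey <- function(u, v) paste(min(ids[u], ids[v]), max(ids[u], ids[v]))
  for (i in seq_len(n_edges(g)))
    edge_bw[[paste(min(g$edges$source[i], g$edges$target[i]),
                   max(g$edges$source[i], g$edges$target[i]))]] <- 0
  if (n >= 2) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      paths <- oracle_all_paths(A, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, function(p) path_len(A, p), numeric(1))
      dmin <- min(lens)
      D[s, t] <- D[t, s] <- dmin
      sp <- paths[lens < dmin + 1e-9]
      for (p in sp) {
        inner <- p[-c(1, length(p))]
        for (v in inner) {
          node_bw[ids[v]] <- node_bw[ids[v]] + 1 / length(sp)
          node_load[ids[v]] <- node_load[ids[v]] + 1
        }
        for (j in seq_len(length(p) - 1)) {
          k <- ekey(p[j], p[j + 1])
          edge_bw[[k]] <- edge_bw[[k]] + 1 / length(sp)
        }
      }
    }
  }
  finite <- is.finite(D) & upper.tri(D)
  closeness <- stats::setNames(rep(NA_real_, n), ids)
  for (v in seq_len(n)) {
    dsum <- sum(D[v, is.finite(D[v, ]) & seq_len(n) != v])
    reach <- sum(is.finite(D[v, ])) - 1
    if (reach > 0) closeness[v] <- 1 / dsum
  }
  list(D = D,
       diameter = if (any(finite)) max(D[finite]) else NA_real_,
       apl = if (any(finite)) mean(D[finite]) else NA_real_,
       node_betweenness = node_bw,
       node_load = node_load,
       edge_betweenness = unlist(edge_bw),
       closeness = closeness)
}

# seeded random connected graph with n <= nmax nodes (for property sweeps)
random_small_graph <- function(seed, nmax = 8, weighted = FALSE) {
  set.seed(seed)
  repeat {
    n <- sample(4:nmax, 1)
    p <- stats::runif(1, 0.3, 0.8)
    pr <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pr)) < p
    if (!any(keep)) next
    ids <- sprintf("v%02d", seq_len(n))
    w <- if (weighted) round(stats::runif(sum(keep), 0.5, 3), 2) else
      rep(1, sum(keep))
    g <- nv_graph(data.frame(source = ids[pr[keep, 1]],
                             target = ids[pr[keep, 2]], weight = w),
                  data.frame(id = ids))
    if (length(connected_components(g)) == 1) return(g)
  }
}

# dense-eigendecomposition Fiedler oracle: the eigenspace of the second
# smallest Laplacian eigenvalue (can be degenerate)
oracle_fiedler_space <- function(g) {
  A <- oracle_adj(g)
  L <- diag(rowSums(A)) - A
  es <- eigen(L, symmetric = TRUE)
  vals <- rev(es$values)
  vecs <- es$vectors[, rev(seq_len(ncol(es$vectors))), drop = FALSE]
  lambda2 <- vals[2]
  sel <- abs(vals - lambda2) < 1e-8
  list(lambda = lambda2, space = vecs[, sel, drop = FALSE])
}

# brute-force minimum balanced cut over all balanced sign vectors
oracle_min_balanced_cut <- function(g) {
  ids <- node_ids(g)
  n <- length(ids)
  A <- oracle_adj(g)
  best <- NULL; best_cut <- Inf
  for (mask in 0:(2^n - 1)) {
    side <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    if (abs(sum(side) - (n - sum(side))) > 1) next
    cut <- sum(A[side, !side, drop = FALSE])
    if (cut < best_cut) { best_cut <- cut; best <- side }
  }
  list(parts = list(sort(ids[best]), sort(ids[!best])), cut = best_cut)
}

# double-loop r-PolyLog energy, independent of the compiled kernel
oracle_linlog_energy <- function(pos, g, r, mode = "node") {
  ids <- node_ids(g)
  deg <- node_degrees(g)
  att <- 0
  for (i in seq_len(n_edges(g))) {
    d <- sqrt(sum((pos[g$edges$source[i], ] - pos[g$edges$target[i], ])^2))
    att <- att + d^r / r
  }
  rep_ <- 0
  n <- length(ids)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pos[ids[i], ] - pos[ids[j], ])^2))
    wfac <- if (mode == "edge") deg[ids[i]] * deg[ids[j]] else 1
    rep_ <- rep_ + wfac * log(d)
  }
  unname(att - rep_)
}

# bare coordinate matrix of a layout (drop class and diagnostic attributes)
layout_coords <- function(l) {
  m <- unclass(l)
  matrix(m, nrow(m), 3, dimnames = dimnames(m))
}

# exact-agreement check between a partition and planted truth
partitions_equal <- function(p, truth) {
  m <- p$membership[names(truth$membership)]
  p$k == truth$k &&
    length(unique(paste(m, truth$membership))) == truth$k
}
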
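# Seven 3D layout engines.  All of them return an `nv_layout`: an n x 3
# coordinate matrix (rownames = node ids) with a `volume` attribute, and all
# are deterministic for a fixed seed.

.golden_angle <- pi * (3 - sqrt(5))

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Construct a layout object
#' @param pos numeric matrix, one row per node, 2 or 3 columns; rownames are
#'   node ids (2-column input is padded with z = 0)
#' @param volume bounding-box volume of the layout space
#' @export
nv_layout <- function(pos, volume = 1000) {
  pos <- as.matrix(pos)
  if (ncol(pos) == 2) pos <- cbind(pos, 0)
  stopifnot(ncol(pos) == 3, all(is.finite(pos)) || nrow(pos) == 0)
  colnames(pos) <- c("x", "y", "z")
  structure(pos, volume = volume, class = "nv_layout")
}

#' @export
print.nv_layout <- function(x, ...) {
  cat(sprintf("<nv_layout> %d positions, volume %g\n", nrow(x),
              attr(x, "volume")))
  invisible(x)
}

# zero-based m x 2 edge index matrix aligned with g$nodes order
.edge_index <- function(g) {
  idx <- cbind(match(g$edges$source, g$nodes$id),
               match(g$edges$target, g$nodes$id)) - 1L
  storage.mode(idx) <- "integer"
  if (n_edges(g) == 0) idx <- matrix(integer(0), 0, 2)
  idx
}

# random start inside the layout cube, coincident nodes separated
.init_positions <- function(n, side, dims = 3) {
  matrix(stats::runif(n * dims, -side / 2, side / 2), n, dims)
}

.jitter_coincident <- function(pos, k) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  bad <- which(apply(d, 1, min) < 1e-9)
  if (length(bad) > 0)
    pos[bad, ] <- pos[bad, , drop = FALSE] +
      matrix(stats::runif(length(bad) * ncol(pos), -1, 1) * 1e-4 * k,
             length(bad), ncol(pos))
  pos
}

#' Force-directed layout parameters
#'
#' \code{k = (volume / n)^(1/3)} is the equilibrium edge length.  The
#' iteration budget is size-adaptive (non-increasing in n):
#' \code{min(1000, max(50, 30 * ceiling(1e4 / n)))}.  Temperature decays
#' linearly from \code{initial_step} to zero unless a multiplicative
#' \code{cooling} factor in (0,1) is supplied.
#'
#' @param volume layout cube volume (cubic layout units)
#' @param iterations iteration budget; \code{NULL} for the size-adaptive rule
#' @param initial_step starting temperature (maximum per-step displacement);
#'   \code{NULL} defaults to k
#' @param cooling optional multiplicative cooling factor in (0,1)
#' @param seed RNG seed for the random start
#' @export
fr_params <- function(volume = 1000, iterations = NULL, initial_step = NULL,
                      cooling = NULL, seed = 1) {
  stopifnot(volume > 0, is.null(cooling) || (cooling > 0 && cooling < 1))
  structure(list(volume = volume, iterations = iterations,
                 initial_step = initial_step, cooling = cooling, seed = seed),
            class = "fr_params")
}

.fr_budget <- function(n, iterations = NULL) {
  if (!is.null(iterations)) return(as.integer(iterations))
  as.integer(min(1000, max(50, 30 * ceiling(1e4 / max(n, 1)))))
}

#' Fruchterman-Reingold force pair
#'
#' The attractive and repulsive force magnitudes acting between two nodes at
#' distance \code{d} with equilibrium length \code{k}:
#' \code{f_a = d^2 / k} and \code{f_r = -k^2 / d}.  The two magnitudes are
#' equal (up to sign) exactly at \code{d = k}.
#'
#' @param d positive distance
#' @param k positive equilibrium length
#' @return named vector \code{c(attractive, repulsive)}
#' @export
fr_forces <- function(d, k) {
  stopifnot(all(d > 0), k > 0)
  c(attractive = d^2 / k, repulsive = -k^2 / d)
}

# per-node net-force magnitude sum (used as the FR stress diagnostic)
.fr_stress <- function(pos, eidx, k, wattr) {
  disp <- fr_displacement(pos, eidx, k, wattr)
  sum(sqrt(rowSums(disp^2)))
}

# shared iterate loop for FR-family layouts.  temps: per-iteration
# displacement caps; wattr_fn(it, lengths) returns per-edge attraction
# scales (1 = plain FR).  Positions are clamped to the layout cube.
.fr_iterate <- function(pos, eidx, k, temps, side, wattr_fn = NULL,
                        dims = ncol(pos)) {
  m <- nrow(eidx)
  ones <- rep(1, m)
  for (it in seq_along(temps)) {
    wattr <- if (is.null(wattr_fn)) ones else {
      len <- sqrt(rowSums((pos[eidx[, 1] + 1L, , drop = FALSE] -
                           pos[eidx[, 2] + 1L, , drop = FALSE])^2))
      wattr_fn(it, len)
    }
    disp <- fr_displacement(pos, eidx, k, wattr)
    mag <- sqrt(rowSums(disp^2))
    scale <- ifelse(mag > 0, pmin(mag, temps[it]) / pmax(mag, 1e-12), 0)
    pos <- pos + disp * scale
  }
  .fit_to_cube(pos, side)
}

# uniform rescale about the centroid so the layout fits the cube; uniform,
# so distance ratios (cluster separation vs spread) are preserved
.fit_to_cube <- function(pos, side) {
  if (nrow(pos) < 2) return(pos)
  ctr <- colMeans(pos)
  pos <- sweep(pos, 2, ctr)
  ext <- max(abs(pos))
  if (ext > side / 2) pos <- pos * (side / 2) / ext
  pos
}

.fr_temps <- function(t0, iters, cooling = NULL) {
  if (is.null(cooling)) t0 * (1 - (seq_len(iters) - 1) / iters)
  else t0 * cooling^(seq_len(iters) - 1)
}

#' 3D force-directed (Fruchterman-Reingold) layout
#'
#' Nodes repel like charged particles (\code{k^2/d}) and edges pull like
#' springs (\code{d^2/k}); the layout settles where the two balance, i.e.
#' adjacent nodes at separation about \code{k = (volume/n)^(1/3)}.
#'
#' @param g an \code{nv_graph}
#' @param params an \code{\link{fr_params}} object
#' @return an \code{nv_layout}; attribute \code{stress} holds
#'   \code{c(initial, final)} total net-force magnitude
#' @export
layout_force_directed <- function(g, params = fr_params()) {
  n <- n_nodes(g)
  if (n == 0) return(nv_layout(matrix(0, 0, 3), params$volume))
  side <- params$volume^(1 / 3)
  if (n == 1) {
    l <- nv_layout(matrix(0, 1, 3), params$volume)
    rownames(l) <- g$nodes$id
    attr(l, "stress") <- c(initial = 0, final = 0)
    return(l)
  }
  k <- (params$volume / n)^(1 / 3)
  eidx <- .edge_index(g)
  iters <- .fr_budget(n, params$iterations)
  t0 <- if (is.null(params$initial_step)) k else params$initial_step
  with_seed(params$seed, {
    pos <- .jitter_coincident(.init_positions(n, side), k)
    s0 <- .fr_stress(pos, eidx, k, rep(1, nrow(eidx)))
    pos <- .fr_iterate(pos, eidx, k, .fr_temps(t0, iters, params$cooling),
                       side)
    s1 <- .fr_stress(pos, eidx, k, rep(1, nrow(eidx)))
    rownames(pos) <- g$nodes$id
    l <- nv_layout(pos, params$volume)
    attr(l, "stress") <- c(initial = s0, final = s1)
    l
  })
}

# ---- lin-log -------------------------------------------------------------

#' r-PolyLog layout parameters
#'
#' The r-PolyLog energy family: attraction \code{(1/r)||p(u)-p(v)||^r} summed
#' over edges minus logarithmic repulsion over all node pairs.  At r = 1 this
#' is the LinLog model (cluster-separating); at r = 3 its single-edge
#' equilibrium matches plain FR with k = 1.  Mode \code{"edge"} weights the
#' repulsion of each pair by \code{deg(u) deg(v)}.
#'
#' @param r positive exponent (default 1, the LinLog model)
#' @param mode \code{"node"} or \code{"edge"} repulsion
#' @param iterations optimizer step budget
#' @param seed RNG seed for the random start
#' @export
linlog_params <- function(r = 1, mode = c("node", "edge"), iterations = 400,
                          seed = 1) {
  stopifnot(r > 0)
  structure(list(r = r, mode = match.arg(mode), iterations = iterations,
                 seed = seed), class = "linlog_params")
}

.repulsion_weights <- function(g, mode) {
  if (mode == "edge") pmax(as.numeric(node_degrees(g)), 1e-12)
  else rep(1, n_nodes(g))
}

#' r-PolyLog energy of a layout
#'
#' @param layout an \code{nv_layout} covering the graph's nodes
#' @param g an \code{nv_graph}
#' @param params a \code{\link{linlog_params}} object
#' @return scalar energy; an error if two nodes coincide (jitter the layout)
#' @export
linlog_energy <- function(layout, g, params = linlog_params()) {
  pos <- unclass(layout)[g$nodes$id, , drop = FALSE]
  e <- linlog_energy_cpp(pos, .edge_index(g), params$r,
                         .repulsion_weights(g, params$mode))
  if (!is.finite(e))
    stop("coincident nodes give infinite repulsion; jitter the layout")
  e
}

#' Lin-log (r-PolyLog) layout
#'
#' Gradient descent on the r-PolyLog energy with adaptive step halving: a
#' step that increases the energy is rejected and the step size halved, so
#' the energy is non-increasing over accepted steps.
#'
#' @inheritParams linlog_energy
#' @return an \code{nv_layout}; attribute \code{energy} holds the final value
#' @export
layout_linlog <- function(g, params = linlog_params()) {
  n <- n_nodes(g)
  if (n == 0) return(nv_layout(matrix(0, 0, 3), 1))
  side <- max(1, n^(1 / 3))
  eidx <- .edge_index(g)
  repw <- .repulsion_weights(g, params$mode)
  with_seed(params$seed, {
    pos <- .jitter_coincident(.init_positions(n, side), side / 10)
    en <- linlog_energy_cpp(pos, eidx, params$r, repw)
    step <- 0.05 * side
    for (it in seq_len(params$iterations)) {
      gr <- linlog_gradient(pos, eidx, params$r, repw)
      mag <- sqrt(rowSums(gr^2))
      top <- max(mag, 1e-12)
      cand <- pos - gr * (step / top)
      en_new <- linlog_energy_cpp(cand, eidx, params$r, repw)
      if (is.finite(en_new) && en_new <= en) {
        pos <- cand
        en <- en_new
        step <- min(step * 1.1, side)
      } else {
        step <- step / 2
        if (step < 1e-12) break
      }
    }
    rownames(pos) <- g$nodes$id
    l <- nv_layout(pos, side^3)
    attr(l, "energy") <- en
    l
  })
}

# ---- spectral bisection and hybrid layout --------------------------------

#' Balanced spectral bisection by the Fiedler vector
#'
#' Solves \code{L q = lambda q} for the second-smallest eigenpair of the
#' (weighted) graph Laplacian by power iteration: the constant vector is
#' projected out and power iteration run on \code{sigma I - L} with sigma a
#' Gershgorin bound, so the Fiedler pair dominates.  The two parts come from
#' splitting at the median Fiedler value (ties to part A), which guarantees
#' \code{|#A - #B| <= 1} as the partition step requires equal sizes.
#'
#' @param g a connected \code{nv_graph} with at least 2 nodes
#' @return list with \code{q} (+1/-1 over nodes, named), \code{lambda},
#'   \code{fiedler} (the eigenvector), and \code{parts} (list of two id sets)
#' @export
spectral_bisect <- function(g) {
  n <- n_nodes(g)
  if (n < 2) stop("need at least 2 nodes")
  if (length(connected_components(g)) != 1)
    stop("graph is disconnected; bisect each component separately")
  ids <- g$nodes$id
  eidx <- .edge_index(g) + 1L
  w <- g$edges$weight
  L <- matrix(0, n, n)
  for (e in seq_len(nrow(eidx))) {
    i <- eidx[e, 1]; j <- eidx[e, 2]
    L[i, j] <- L[i, j] - w[e]
    L[j, i] <- L[j, i] - w[e]
    L[i, i] <- L[i, i] + w[e]
    L[j, j] <- L[j, j] + w[e]
  }
  sigma <- 2 * max(diag(L)) + 1
  x <- sin(seq_len(n))          # fixed deterministic start
  x <- x - mean(x)
  x <- x / sqrt(sum(x^2))
  for (it in seq_len(50000)) {
    y <- sigma * x - drop(L %*% x)
    y <- y - mean(y)
    ny <- sqrt(sum(y^2))
    if (ny < 1e-300) { y <- cos(seq_len(n)); y <- y - mean(y); ny <- sqrt(sum(y^2)) }
    y <- y / ny
    if (max(abs(y - x)) < 1e-13 || max(abs(y + x)) < 1e-13) { x <- y; break }
    x <- y
  }
  lambda <- drop(crossprod(x, L %*% x))
  ord <- order(x, ids)
  a_size <- ceiling(n / 2)
  q <- stats::setNames(rep(-1, n), ids)
  q[ids[ord[seq_len(a_size)]]] <- 1
  list(q = q, lambda = lambda, fiedler = stats::setNames(x, ids),
       parts = list(A = sort(ids[ord[seq_len(a_size)]]),
                    B = sort(ids[ord[-seq_len(a_size)]])))
}

.bbox_offset <- function(layouts) {
  # place part layouts side by side along the axis of largest combined
  # extent, separated by one part-diameter
  ext <- sapply(layouts, function(p) apply(p, 2, function(v)
    if (length(v) == 0) 0 else diff(range(v))))
  axis <- which.max(rowSums(matrix(ext, nrow = 3)))
  gap <- max(sapply(layouts, function(p)
    if (nrow(p) == 0) 0 else max(stats::dist(p), 0)))
  gap <- max(gap, 1)
  cursor <- 0
  out <- list()
  for (p in layouts) {
    if (nrow(p) > 0) {
      p <- sweep(p, 2, colMeans(p))
      half <- diff(range(p[, axis])) / 2
      p[, axis] <- p[, axis] + cursor + half
      cursor <- cursor + 2 * half + gap
    }
    out <- c(out, list(p))
  }
  res <- do.call(rbind, out)
  sweep(res, 2, colMeans(res))
}

.induced_subgraph <- function(g, ids) {
  keep <- g$edges$source %in% ids & g$edges$target %in% ids
  nv_graph(g$edges[keep, , drop = FALSE],
           g$nodes[g$nodes$id %in% ids, , drop = FALSE])
}

#' Hybrid force-directed layout
#'
#' Three steps: random initial positions, balanced spectral bisection of the
#' graph, then an independent FR layout of each part.  The two sub-layouts
#' are placed side by side (non-overlapping bounding boxes) along the axis of
#' largest extent.  Disconnected graphs are partitioned into their
#' components instead of bisected.
#'
#' @inheritParams layout_force_directed
#' @export
layout_hybrid <- function(g, params = fr_params()) {
  n <- n_nodes(g)
  if (n == 0) return(nv_layout(matrix(0, 0, 3), params$volume))
  if (n == 1) {
    l <- nv_layout(matrix(0, 1, 3), params$volume)
    rownames(l) <- g$nodes$id
    return(l)
  }
  comps <- connected_components(g)
  parts <- if (length(comps) == 1) spectral_bisect(g)$parts else comps
  sub <- lapply(parts, function(ids) {
    sg <- .induced_subgraph(g, ids)
    p <- fr_params(volume = params$volume * length(ids) / n,
                   iterations = params$iterations,
                   initial_step = params$initial_step,
                   cooling = params$cooling, seed = params$seed)
    unclass(layout_force_directed(sg, p))[, 1:3, drop = FALSE]
  })
  pos <- .bbox_offset(sub)
  l <- nv_layout(pos[g$nodes$id, , drop = FALSE], params$volume)
  attr(l, "parts") <- parts
  l
}

# ---- coarsened layout ----------------------------------------------------

#' Coarsening parameters
#' @param min_size stop when the coarse graph has at most this many nodes
#' @param rate stop when a round shrinks the node count by less than this
#'   factor (new/old ratio above \code{rate})
#' @param seed seed for the randomized matching order
#' @export
coarsen_params <- function(min_size = 3, rate = 0.75, seed = 1) {
  stopifnot(min_size >= 1, rate > 0, rate < 1)
  structure(list(min_size = min_size, rate = rate, seed = seed),
            class = "coarsen_params")
}

# one round of randomized heavy-edge matching; returns named map id -> coarse id
.heavy_edge_match <- function(g) {
  ids <- g$nodes$id
  deg <- node_degrees(g)
  nbr <- .adjacency_list(g)
  matched <- stats::setNames(rep(FALSE, length(ids)), ids)
  map <- stats::setNames(ids, ids)
  visit <- sample(ids)
  for (u in visit) {
    if (matched[u]) next
    nb <- nbr[[u]]
    nb <- nb[!matched[nb$id], , drop = FALSE]
    if (nrow(nb) == 0) { matched[u] <- TRUE; next }
    pick <- nb$id[order(-nb$w, nb$id)][1]   # heaviest edge, ties by id
    cid <- min(u, pick)
    map[u] <- cid; map[pick] <- cid
    matched[u] <- TRUE; matched[pick] <- TRUE
  }
  map
}

.adjacency_list <- function(g) {
  out <- lapply(stats::setNames(vector("list", n_nodes(g)), g$nodes$id),
                function(x) data.frame(id = character(), w = numeric()))
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    out[[e$source[i]]] <- rbind(out[[e$source[i]]],
                                data.frame(id = e$target[i], w = e$weight[i]))
    out[[e$target[i]]] <- rbind(out[[e$target[i]]],
                                data.frame(id = e$source[i], w = e$weight[i]))
  }
  out
}

.contract <- function(g, map) {
  e <- g$edges
  src <- unname(map[e$source]); tgt <- unname(map[e$target])
  keep <- src != tgt
  ne <- data.frame(source = src[keep], target = tgt[keep],
                   weight = e$weight[keep], stringsAsFactors = FALSE)
  suppressWarnings(
    nv_graph(ne, nodes = data.frame(id = sort(unique(unname(map))))))
}

#' Coarsen a graph by repeated heavy-edge matching
#'
#' @param g an \code{nv_graph}
#' @param params a \code{\link{coarsen_params}} object
#' @return list of levels, finest first; each level is
#'   \code{list(graph, map)} where \code{map} sends the previous (finer)
#'   level's ids to this level's ids (\code{NULL} at level 1)
#' @export
coarsen <- function(g, params = coarsen_params()) {
  levels <- list(list(graph = g, map = NULL))
  with_seed(params$seed, {
    cur <- g
    repeat {
      if (n_nodes(cur) <= params$min_size) break
      map <- .heavy_edge_match(cur)
      nxt <- .contract(cur, map)
      if (n_nodes(nxt) / n_nodes(cur) > params$rate) break
      levels[[length(levels) + 1L]] <- list(graph = nxt, map = map)
      cur <- nxt
    }
  })
  levels
}

#' Multilevel (coarsened) force-directed layout
#'
#' The graph is coarsened by heavy-edge matching until the minimum size or
#' coarsening-rate stop rule fires; the coarsest graph is laid out by FR, and
#' each finer level starts from its parent's positions (plus a small jitter
#' to separate merged nodes) and is refined with a reduced FR budget.
#'
#' @param g an \code{nv_graph}
#' @param cparams a \code{\link{coarsen_params}} object
#' @param params an \code{\link{fr_params}} object
#' @export
layout_coarsened <- function(g, cparams = coarsen_params(),
                             params = fr_params()) {
  n <- n_nodes(g)
  if (n == 0) return(nv_layout(matrix(0, 0, 3), params$volume))
  levels <- coarsen(g, cparams)
  if (length(levels) == 1) return(layout_force_directed(g, params))
  side <- params$volume^(1 / 3)
  k <- (params$volume / n)^(1 / 3)
  coarsest <- levels[[length(levels)]]$graph
  pos <- unclass(layout_force_directed(coarsest, params))[, 1:3, drop = FALSE]
  refine_iters <- max(25L, as.integer(0.3 * .fr_budget(n, params$iterations)))
  with_seed(params$seed + 1L, {
    for (lev in rev(seq_len(length(levels) - 1L))) {
      fine <- levels[[lev]]$graph
      map <- levels[[lev + 1L]]$map
      fpos <- pos[unname(map[fine$nodes$id]), , drop = FALSE] +
        matrix(stats::runif(3 * n_nodes(fine), -1, 1) * 0.01 * k,
               n_nodes(fine), 3)
      rownames(fpos) <- fine$nodes$id
      t0 <- if (is.null(params$initial_step)) k else params$initial_step
      fpos <- .fr_iterate(fpos, .edge_index(fine),
                          (params$volume / n_nodes(fine))^(1 / 3),
                          .fr_temps(0.3 * t0, refine_iters), side)
      pos <- fpos
    }
  })
  l <- nv_layout(pos[g$nodes$id, , drop = FALSE], params$volume)
  attr(l, "levels") <- length(levels)
  l
}

# ---- simulated annealing layout ------------------------------------------

#' Annealing schedule for the edge-cutting layout
#'
#' Five named phases split a total FR iteration budget: liquid 25\%,
#' expansion 25\%, cooldown 25\%, crunch 10\%, simmer 15\%.  Each phase
#' carries a temperature multiplier, an attraction scale and a damping
#' factor applied on top of the linearly decaying FR temperature envelope;
#' all three default to 1 so that \code{edge_cut = 0} reproduces the plain
#' FR trajectory exactly, as the edge-cut semantics require.  Edge cutting
#' ramps with overall progress: at each iteration the attraction of the
#' longest \code{ceiling(edge_cut * m * progress)} edges is suppressed.
#'
#' @param edge_cut fraction in [0,1]; 0 = no cutting (standard FR), 1 =
#'   aggressive cutting of long edges so clusters separate
#' @param iterations total budget (NULL = size-adaptive FR rule)
#' @param phases data.frame(name, frac, temp, attract, damping) overriding
#'   the default five phases
#' @param volume,seed as in \code{\link{fr_params}}
#' @export
anneal_schedule <- function(edge_cut = 0.8, iterations = NULL, phases = NULL,
                            volume = 1000, seed = 1) {
  if (edge_cut < 0 || edge_cut > 1) stop("edge_cut must be in [0, 1]")
  if (is.null(phases))
    phases <- data.frame(
      name = c("liquid", "expansion", "cooldown", "crunch", "simmer"),
      frac = c(0.25, 0.25, 0.25, 0.10, 0.15),
      temp = 1, attract = 1, damping = 1,
      cut = c(0, 1, 1, 0, 0),   # cutting only in the middle phases
      stringsAsFactors = FALSE)
  if (is.null(phases$cut)) phases$cut <- 1
  stopifnot(nrow(phases) >= 1)
  structure(list(edge_cut = edge_cut, iterations = iterations,
                 phases = phases, volume = volume, seed = seed),
            class = "anneal_schedule")
}

#' Simulated-annealing force-directed layout with edge cutting
#'
#' FR run through the five-phase schedule of \code{\link{anneal_schedule}}.
#' With \code{edge_cut = 0} no attraction is ever suppressed and the result
#' equals \code{\link{layout_force_directed}} with the same seed and budget;
#' with \code{edge_cut} near 1 the longest edges lose their attraction each
#' step, letting densely connected groups drift apart.
#'
#' @param g an \code{nv_graph}
#' @param schedule an \code{\link{anneal_schedule}}
#' @export
layout_annealed <- function(g, schedule = anneal_schedule()) {
  n <- n_nodes(g)
  if (n == 0) return(nv_layout(matrix(0, 0, 3), schedule$volume))
  side <- schedule$volume^(1 / 3)
  if (n == 1) {
    l <- nv_layout(matrix(0, 1, 3), schedule$volume)
    rownames(l) <- g$nodes$id
    return(l)
  }
  k <- (schedule$volume / n)^(1 / 3)
  eidx <- .edge_index(g)
  m <- nrow(eidx)
  total <- .fr_budget(n, schedule$iterations)
  ph <- schedule$phases
  counts <- diff(round(cumsum(c(0, ph$frac)) / sum(ph$frac) * total))
  counts[length(counts)] <- total - sum(counts[-length(counts)])
  temps <- .fr_temps(k, total) *
    rep(ph$temp, counts) * rep(ph$damping, counts)
  attract <- rep(ph$attract, counts)
  cutph <- rep(ph$cut, counts)
  cut <- schedule$edge_cut
  # "long" edges lose their attraction during the cutting phases: an edge is
  # cut when its current length is an upper outlier of the length
  # distribution, mean + sd/edge_cut, so edge_cut = 1 cuts aggressively
  # (anything one sd above the mean) and small values only extreme outliers
  wattr_fn <- function(it, len) {
    w <- rep(attract[it], length(len))
    ec <- cut * cutph[it]
    if (ec > 0 && length(len) > 2)
      w[len > mean(len) + stats::sd(len) / ec] <- 0
    w
  }
  with_seed(schedule$seed, {
    pos <- .jitter_coincident(.init_positions(n, side), k)
    pos <- .fr_iterate(pos, eidx, k, temps, side,
                       wattr_fn = if (cut == 0 &&
                                      all(ph$attract == 1)) NULL else wattr_fn)
    rownames(pos) <- g$nodes$id
    nv_layout(pos, schedule$volume)
  })
}

# ---- semantic levels layout ----------------------------------------------

#' Semantic-levels parameters
#' @param n_layers number of equidistant z-levels (default 7)
#' @param spacing z-distance between consecutive levels
#' @param user_layers optional named vector node id -> layer index in
#'   [0, n_layers); honored verbatim when supplied
#' @export
semantic_params <- function(n_layers = 7, spacing = 5, user_layers = NULL) {
  stopifnot(n_layers >= 1, spacing > 0)
  structure(list(n_layers = n_layers, spacing = spacing,
                 user_layers = user_layers), class = "semantic_params")
}

#' Assign nodes to semantic layers
#'
#' User-supplied layers are honored verbatim.  Otherwise nodes are ranked by
#' decreasing degree (ties by ascending id) and cut into \code{n_layers}
#' consecutive bands: cut points start at equal-size rank quantiles and are
#' moved to the nearest degree-tie boundary so nodes of equal degree share a
#' layer whenever every layer can stay non-empty; when a tie group spans a
#' whole band (e.g. a regular graph), it is split by id order.  Layer 0
#' holds the highest-degree nodes.
#'
#' @param g an \code{nv_graph}
#' @param params a \code{\link{semantic_params}} object
#' @return named integer vector node id -> layer index
#' @export
assign_semantic_layers <- function(g, params = semantic_params()) {
  n <- n_nodes(g)
  ids <- g$nodes$id
  L <- params$n_layers
  if (!is.null(params$user_layers)) {
    ul <- params$user_layers
    if (any(ul < 0 | ul >= L)) stop("user layer index out of range")
    missing <- setdiff(ids, names(ul))
    if (length(missing) > 0) stop("user_layers missing nodes: ",
                                  paste(missing, collapse = ", "))
    return(ul[ids])
  }
  if (n == 0) return(stats::setNames(integer(0), character(0)))
  deg <- node_degrees(g)
  ord <- order(-deg, ids)
  dsort <- deg[ord]
  nominal <- round(seq_len(L - 1) * n / L)
  cuts <- nominal
  for (j in seq_along(cuts)) {
    cj <- cuts[j]
    if (cj >= 1 && cj < n && dsort[cj] == dsort[cj + 1]) {
      grp <- which(dsort == dsort[cj])
      lo <- min(grp) - 1L; hi <- max(grp)
      cuts[j] <- if (cj - lo <= hi - cj) lo else hi
    }
  }
  # repair so every layer stays non-empty (strictly increasing cuts in [1, n-1])
  prev <- 0L
  for (j in seq_along(cuts)) {
    hi_allowed <- n - (L - j)
    if (cuts[j] <= prev || cuts[j] > hi_allowed)
      cuts[j] <- max(prev + 1L, min(nominal[j], hi_allowed))
    prev <- cuts[j]
  }
  layer <- integer(n)
  bounds <- c(0L, cuts, n)
  for (b in seq_len(L))
    layer[ord[(bounds[b] + 1L):bounds[b + 1L]]] <- b - 1L
  stats::setNames(layer, ids)
}

#' Semantic-levels layout
#'
#' A 2D FR pass over the whole graph fixes x and y; z is exactly
#' \code{layer * spacing} from \code{\link{assign_semantic_layers}}.  Each
#' layer's induced subgraph is then re-relaxed in its own plane with 20\% of
#' the global budget.
#'
#' @param g an \code{nv_graph}
#' @param sparams a \code{\link{semantic_params}} object
#' @param params an \code{\link{fr_params}} object
#' @export
layout_semantic <- function(g, sparams = semantic_params(),
                            params = fr_params()) {
  n <- n_nodes(g)
  if (n == 0) return(nv_layout(matrix(0, 0, 3), params$volume))
  layer <- assign_semantic_layers(g, sparams)
  side <- params$volume^(1 / 3)
  k <- (params$volume / n)^(1 / 3)
  iters <- .fr_budget(n, params$iterations)
  t0 <- if (is.null(params$initial_step)) k else params$initial_step
  with_seed(params$seed, {
    xy <- .jitter_coincident(.init_positions(n, side, dims = 2), k)
    rownames(xy) <- g$nodes$id
    if (n > 1)
      xy <- .fr_iterate(xy, .edge_index(g), k,
                        .fr_temps(t0, iters, params$cooling), side)
    refine <- max(10L, as.integer(0.2 * iters))
    for (li in sort(unique(layer))) {
      ids <- names(layer)[layer == li]
      if (length(ids) < 2) next
      sg <- .induced_subgraph(g, ids)
      sub <- xy[sg$nodes$id, , drop = FALSE]
      sub <- .fr_iterate(sub, .edge_index(sg),
                         (params$volume / length(ids))^(1 / 3),
                         .fr_temps(0.3 * t0, refine), side)
      xy[sg$nodes$id, ] <- sub
    }
    pos <- cbind(xy, layer[rownames(xy)] * sparams$spacing)
    l <- nv_layout(pos, params$volume)
    attr(l, "layers") <- layer
    l
  })
}

# ---- hemispherical layout ------------------------------------------------

#' Hemisphere specification
#' @param R positive radius
#' @param center 3-vector center of the hemisphere base
#' @export
hemisphere_spec <- function(R = 10, center = c(0, 0, 0)) {
  stopifnot(R > 0, length(center) == 3, all(is.finite(center)))
  structure(list(R = R, center = center), class = "hemisphere_spec")
}

#' Position on the hemispherical spiral
#'
#' Rank 0 sits at the pole (latitude 90 degrees, i.e. \code{center +
#' (0,0,R)}); later ranks descend a Fibonacci spiral with latitude spaced
#' uniformly in \code{sin(latitude)} (equal-area) down to the rim, longitude
#' advancing by the golden angle.  Coordinates follow
#' \code{x = R cos(lat) cos(lon)}, \code{y = R sin(lon) cos(lat)},
#' \code{z = R sin(lat)}.
#'
#' @param rank 0-based placement index
#' @param n total number of nodes
#' @param spec a \code{\link{hemisphere_spec}}
#' @return numeric 3-vector
#' @export
hemisphere_position <- function(rank, n, spec = hemisphere_spec()) {
  if (rank < 0 || rank >= n) stop("rank out of range [0, n)")
  # rank 0 sits exactly on the pole; later ranks descend uniformly in
  # sin(latitude) (equal-area) with a 0.8-cell offset that keeps rank 1
  # clear of the pole and the whole spiral near-uniformly spaced
  sinlat <- if (rank == 0) 1 else 1 - (rank + 0.8) / n
  if (sinlat >= 1) return(spec$center + c(0, 0, spec$R))  # exact pole
  lat <- asin(sinlat)
  lon <- (rank * .golden_angle) %% (2 * pi)
  spec$center + spec$R * c(cos(lat) * cos(lon), sin(lon) * cos(lat), sinlat)
}

#' Hemispherical layout
#'
#' Deterministic: nodes sorted by decreasing degree (ties by ascending id)
#' and placed along the hemisphere spiral, the highest-degree node at the
#' pole.  All nodes satisfy \code{||p - center|| = R}.
#'
#' @param g an \code{nv_graph}
#' @param spec a \code{\link{hemisphere_spec}}
#' @export
layout_hemispherical <- function(g, spec = hemisphere_spec()) {
  n <- n_nodes(g)
  if (n == 0) {
    l <- nv_layout(matrix(0, 0, 3), spec$R^3)
    attr(l, "hemisphere") <- spec
    return(l)
  }
  deg <- node_degrees(g)
  ord <- order(-deg, g$nodes$id)
  pos <- t(vapply(seq_len(n) - 1L, hemisphere_position, numeric(3),
                  n = n, spec = spec))
  pos <- pos[order(ord), , drop = FALSE]   # invert the permutation
  pos <- matrix(pos, n, 3)
  rownames(pos) <- g$nodes$id
  l <- nv_layout(pos, (2 * spec$R)^3)
  attr(l, "hemisphere") <- spec
  l
}
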
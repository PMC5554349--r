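# Cluster-level layouts: transparent bubbles positioned force-directed (or
# lin-log) with hemispherical interiors, and the 3D Circos sliced hemisphere.

#' Cluster quotient graph
#'
#' One node per cluster; inter-cluster edges collapse to a single edge whose
#' weight is the count of underlying edges (or their summed weight).
#'
#' @param g an \code{nv_graph}
#' @param partition an \code{nv_partition} covering the graph
#' @param aggregate \code{"count"} or \code{"sum"}
#' @return an \code{nv_graph} whose node ids are cluster labels
#' @export
quotient_graph <- function(g, partition, aggregate = c("count", "sum")) {
  aggregate <- match.arg(aggregate)
  mem <- partition$membership
  cs <- mem[g$edges$source]; ct <- mem[g$edges$target]
  cross <- cs != ct
  e <- data.frame(source = as.character(pmin(cs[cross], ct[cross])),
                  target = as.character(pmax(cs[cross], ct[cross])),
                  weight = if (aggregate == "sum") g$edges$weight[cross]
                  else rep(1, sum(cross)),
                  stringsAsFactors = FALSE)
  nv_graph(e, nodes = data.frame(id = as.character(sort(unique(mem)))))
}

.cluster_radii <- function(sizes, centers) {
  # radius ~ cube root of member count; constant chosen so the largest
  # bubble spans at most 15% of the layout diameter
  base <- sizes^(1 / 3)
  diam <- if (nrow(centers) > 1) max(stats::dist(centers)) else 0
  if (diam <= 0) diam <- 10
  base * (0.15 * diam) / (2 * max(base))
}

#' Bubble cluster layout
#'
#' Cluster centers come from a force-directed (or lin-log, which draws
#' strongly interconnected clusters together) layout of the quotient graph;
#' each cluster's members are arranged on the upper hemisphere of its own
#' transparent bubble, radius proportional to the cube root of cluster size.
#' Centers are rescaled outward until no two bubbles overlap.
#'
#' @param g an \code{nv_graph}
#' @param partition an \code{nv_partition}
#' @param mode \code{"fd"} or \code{"linlog"} for the quotient layout
#' @param aggregate inter-cluster weight rule, see \code{\link{quotient_graph}}
#' @param seed seed for the quotient layout
#' @return list with \code{centers} (k x 3 matrix, rownames = labels),
#'   \code{radii}, \code{node_positions} (\code{nv_layout}), and
#'   \code{slice_bounds = NULL}
#' @export
layout_cluster_bubbles <- function(g, partition, mode = c("fd", "linlog"),
                                   aggregate = "count", seed = 1) {
  mode <- match.arg(mode)
  q <- quotient_graph(g, partition, aggregate)
  kq <- n_nodes(q)
  centers <- if (mode == "fd")
    unclass(layout_force_directed(q, fr_params(seed = seed)))[, 1:3,
                                                              drop = FALSE]
  else unclass(layout_linlog(q, linlog_params(seed = seed)))[, 1:3,
                                                             drop = FALSE]
  centers <- matrix(centers, kq, 3,
                    dimnames = list(q$nodes$id, c("x", "y", "z")))
  sizes <- table(factor(partition$membership, levels = q$nodes$id))
  radii <- stats::setNames(.cluster_radii(as.numeric(sizes), centers),
                           q$nodes$id)
  # grow center separation until bubbles are disjoint
  if (kq > 1) {
    for (pass in seq_len(100)) {
      d <- as.matrix(stats::dist(centers))
      need <- outer(radii, radii, "+") * 1.05
      diag(need) <- 0
      if (all(d >= need - 1e-12)) break
      bad <- d < need & upper.tri(d)
      f <- max(need[bad] / pmax(d[bad], 1e-9))
      ctr <- colMeans(centers)
      centers <- sweep(sweep(centers, 2, ctr) * f, 2, ctr, "+")
      # coincident centers cannot be separated by scaling; nudge apart
      if (any(d[upper.tri(d)] < 1e-9)) {
        set.seed(seed)
        centers <- centers + matrix(stats::runif(kq * 3, -1, 1) *
                                      max(radii), kq, 3)
      }
    }
  }
  pos <- matrix(NA_real_, n_nodes(g), 3, dimnames = list(g$nodes$id, NULL))
  for (lab in q$nodes$id) {
    ids <- names(partition$membership)[partition$membership == as.integer(lab)]
    sub <- .induced_subgraph(g, ids)
    hl <- layout_hemispherical(sub, hemisphere_spec(R = radii[lab],
                                                    center = centers[lab, ]))
    pos[rownames(hl), ] <- unclass(hl)[, 1:3]
  }
  list(centers = centers, radii = radii,
       node_positions = nv_layout(pos, max(1, (4 * max(radii))^3)),
       slice_bounds = NULL)
}

#' 3D Circos cluster layout
#'
#' All nodes share one hemisphere, sliced into pie-like longitude panels,
#' one per cluster, angular width proportional to cluster size.  Slices are
#' ordered by decreasing size (ties by label), except that the cluster
#' containing the globally highest-degree node takes the first slice.
#' Within a slice, members descend from near the pole to the rim in
#' decreasing degree order along the slice's own sub-spiral, so each
#' cluster's most connected node sits nearest the hemisphere center.
#'
#' @param g an \code{nv_graph}
#' @param partition an \code{nv_partition}
#' @param spec a \code{\link{hemisphere_spec}}
#' @return list with \code{centers} (the hemisphere center per cluster),
#'   \code{radii}, \code{node_positions}, \code{slice_bounds} (named list of
#'   \code{c(longitude_start, longitude_end)} in degrees)
#' @export
layout_circos3d <- function(g, partition, spec = hemisphere_spec()) {
  mem <- partition$membership
  labs <- sort(unique(mem))
  sizes <- stats::setNames(as.numeric(table(factor(mem, levels = labs))),
                           labs)
  deg <- node_degrees(g)
  top_cluster <- as.character(mem[names(which.max(deg))[1]])
  ord <- names(sizes)[order(-sizes, names(sizes))]
  ord <- c(top_cluster, setdiff(ord, top_cluster))
  widths <- 360 * sizes[ord] / sum(sizes)
  stops <- cumsum(c(0, widths))
  stops[length(stops)] <- 360
  bounds <- lapply(seq_along(ord), function(i) c(stops[i], stops[i + 1]))
  names(bounds) <- ord
  pos <- matrix(NA_real_, n_nodes(g), 3, dimnames = list(g$nodes$id, NULL))
  for (lab in ord) {
    ids <- names(mem)[mem == as.integer(lab)]
    ids <- ids[order(-deg[ids], ids)]
    nc <- length(ids)
    b <- bounds[[lab]] * pi / 180
    for (i in seq_len(nc)) {
      sinlat <- 1 - (i - 0.5) / nc
      lat <- asin(sinlat)
      frac <- ((i - 1) * .golden_angle / (2 * pi)) %% 1
      lon <- b[1] + frac * (b[2] - b[1])
      pos[ids[i], ] <- spec$center +
        spec$R * c(cos(lat) * cos(lon), sin(lon) * cos(lat), sinlat)
    }
  }
  centers <- matrix(rep(spec$center, each = length(ord)), length(ord), 3,
                    dimnames = list(ord, c("x", "y", "z")))
  lay <- nv_layout(pos, (2 * spec$R)^3)
  attr(lay, "hemisphere") <- spec
  list(centers = centers,
       radii = stats::setNames(rep(spec$R, length(ord)), ord),
       node_positions = lay, slice_bounds = bounds)
}
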
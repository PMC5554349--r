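# Force-directed 3D edge bundling: compatible edges are subdivided and their
# subdivision points attracted toward each other while internal springs keep
# each polyline coherent.  Endpoints never move.

#' Edge-pair compatibility
#'
#' Product of four factors, each in [0,1]: angle (|cos| of the angle between
#' the segments, so antiparallel edges still bundle), scale
#' (\code{2 / (l_avg/l_min + l_max/l_avg)}), position
#' (\code{l_avg / (l_avg + midpoint distance)}), and visibility (how much of
#' each segment's projection onto the other is mutually "visible").
#' Symmetric in its arguments; 1 only for identical segments up to
#' direction, 0 for perpendicular segments.
#'
#' @param p,q 2 x 3 matrices: the two segment endpoints as rows
#' @return scalar in [0, 1]
#' @export
edge_compatibility <- function(p, q) {
  vp <- p[2, ] - p[1, ]; vq <- q[2, ] - q[1, ]
  lp <- sqrt(sum(vp^2)); lq <- sqrt(sum(vq^2))
  if (lp == 0 || lq == 0) stop("zero-length segment")
  ca <- abs(sum(vp * vq)) / (lp * lq)
  lavg <- (lp + lq) / 2
  cs <- 2 / (lavg / min(lp, lq) + max(lp, lq) / lavg)
  mp <- (p[1, ] + p[2, ]) / 2
  mq <- (q[1, ] + q[2, ]) / 2
  cp <- lavg / (lavg + sqrt(sum((mp - mq)^2)))
  cv <- min(.visibility(p, q), .visibility(q, p))
  ca * cs * cp * cv
}

# visibility of q from p: project q's endpoints onto p's line; 0 when the
# midpoint of the projections is further from p's midpoint than half the
# projected span
.visibility <- function(p, q) {
  vp <- p[2, ] - p[1, ]
  t0 <- sum((q[1, ] - p[1, ]) * vp) / sum(vp^2)
  t1 <- sum((q[2, ] - p[1, ]) * vp) / sum(vp^2)
  i0 <- p[1, ] + t0 * vp
  i1 <- p[1, ] + t1 * vp
  im <- (i0 + i1) / 2
  mp <- (p[1, ] + p[2, ]) / 2
  denom <- sqrt(sum((i0 - i1)^2))
  if (denom == 0) return(0)
  max(0, 1 - 2 * sqrt(sum((mp - im)^2)) / denom)
}

#' Bundling parameters
#'
#' Defaults follow the force-directed edge bundling design this
#' implementation is modeled on: compatibility threshold 0.6, 6 cycles with
#' subdivisions doubling and iterations halving each cycle, step size
#' 0.04 x mean edge length (halving each cycle), spring constant K = 0.1.
#'
#' @param compat_threshold pairs below this total compatibility exert no
#'   force on each other
#' @param cycles number of subdivision cycles
#' @param initial_subdivisions base subdivision count: cycle c runs with
#'   \code{initial_subdivisions * 2^c} interior points per edge
#' @param step_size initial point displacement per iteration; \code{NULL}
#'   means 0.04 x mean edge length
#' @param K global spring stiffness
#' @param iterations_per_cycle iterations in cycle 1 (halving each cycle)
#' @export
bundle_params <- function(compat_threshold = 0.6, cycles = 6,
                          initial_subdivisions = 1, step_size = NULL,
                          K = 0.1, iterations_per_cycle = 50) {
  structure(list(compat_threshold = compat_threshold, cycles = cycles,
                 initial_subdivisions = initial_subdivisions,
                 step_size = step_size, K = K,
                 iterations_per_cycle = iterations_per_cycle),
            class = "bundle_params")
}

.subdivide <- function(pts, n_interior) {
  # resample the polyline at n_interior+2 equally spaced arc-length points
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  total <- sum(seg)
  if (total == 0)
    return(matrix(rep(pts[1, ], n_interior + 2), ncol = 3, byrow = TRUE))
  target <- seq(0, total, length.out = n_interior + 2)
  cum <- c(0, cumsum(seg))
  out <- matrix(0, n_interior + 2, 3)
  for (i in seq_along(target)) {
    s <- min(max(findInterval(target[i], cum, rightmost.closed = TRUE), 1),
             length(seg))
    f <- if (seg[s] == 0) 0 else (target[i] - cum[s]) / seg[s]
    out[i, ] <- pts[s, ] + f * (pts[s + 1, ] - pts[s, ])
  }
  out[1, ] <- pts[1, ]
  out[nrow(out), ] <- pts[nrow(pts), ]
  out
}

#' Force-directed edge bundling
#'
#' Each edge becomes a polyline whose interior points feel (i) spring forces
#' from their neighbors along the same edge, stiffness \code{K / (|edge| *
#' n_segments)}, and (ii) electrostatic attraction toward the corresponding
#' points of every edge whose pairwise compatibility exceeds the threshold.
#' Per-point displacement is capped at the cycle's step size.  Endpoints are
#' fixed; the procedure is fully deterministic.  If the layout carries a
#' hemisphere constraint, points are re-projected onto the sphere after each
#' cycle so bundles stay on the surface.
#'
#' @param layout an \code{nv_layout} covering the edge endpoints
#' @param g an \code{nv_graph}
#' @param params a \code{\link{bundle_params}} object
#' @return list of \code{BundledEdge}s: \code{list(source, target, points)}
#'   with \code{points} an ordered point matrix, first/last rows the exact
#'   endpoint positions
#' @export
bundle_edges <- function(layout, g, params = bundle_params()) {
  pos <- unclass(layout)
  m <- n_edges(g)
  if (m == 0) return(list())
  ep1 <- pos[g$edges$source, , drop = FALSE]
  ep2 <- pos[g$edges$target, , drop = FALSE]
  lens <- sqrt(rowSums((ep2 - ep1)^2))
  ok <- lens > 1e-12
  step0 <- if (is.null(params$step_size)) 0.04 * mean(lens[ok]) else
    params$step_size
  hemi <- attr(layout, "hemisphere")

  # pairwise compatibility on the straight segments, computed once
  pairs <- if (m > 1)
    compat_pairs(ep1, ep2, params$compat_threshold)
  else matrix(0, 0, 4)
  has_partner <- rep(FALSE, m)
  has_partner[c(pairs[, 1], pairs[, 2])] <- TRUE

  polylines <- lapply(seq_len(m), function(e) rbind(ep1[e, ], ep2[e, ]))
  n_sub <- params$initial_subdivisions
  step <- step0
  iters <- params$iterations_per_cycle
  for (cycle in seq_len(params$cycles)) {
    n_sub <- n_sub * 2L   # subdivision count after cycle c: initial * 2^c
    polylines <- lapply(polylines, .subdivide, n_interior = n_sub)
    np <- n_sub + 2L
    # springs only act on edges that have a bundling partner; partnerless
    # edges stay exactly straight
    kp <- ifelse(ok & has_partner, params$K / (pmax(lens, 1e-12) * (np - 1)),
                 0)
    pts <- do.call(rbind, polylines)
    pts <- bundle_cycle(pts, m, np, pairs, kp, step,
                        max(1L, as.integer(iters)))
    polylines <- lapply(seq_len(m), function(e)
      pts[((e - 1L) * np + 1L):(e * np), , drop = FALSE])
    if (!is.null(hemi)) {
      polylines <- lapply(seq_len(m), function(e) {
        pl <- polylines[[e]]
        ctr <- matrix(hemi$center, nrow(pl), 3, byrow = TRUE)
        v <- pl - ctr
        r <- sqrt(rowSums(v^2))
        proj <- ctr + v * ifelse(r > 1e-12, hemi$R / r, 0)
        proj[1, ] <- pl[1, ]; proj[nrow(pl), ] <- pl[nrow(pl), ]
        proj
      })
    }
    step <- step / 2
    iters <- iters / 2
  }
  lapply(seq_len(m), function(e) {
    pts <- polylines[[e]]
    pts[1, ] <- ep1[e, ]; pts[nrow(pts), ] <- ep2[e, ]
    list(source = g$edges$source[e], target = g$edges$target[e],
         points = pts)
  })
}
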
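# Headless 3D -> 2D rendering: perspective/orthographic projection, painter's
# depth sort, shaded sphere glyphs, translucent cluster bubbles, arrowheads,
# flat 2D labels with a 1-px halo, PNG snapshots and rotating GIF movies.

#' Camera specification
#' @param eye,look_at,up 3-vectors; eye must differ from look_at and up must
#'   not be parallel to the view direction
#' @param field_of_view vertical field of view in degrees (perspective)
#' @param projection \code{"perspective"} or \code{"orthographic"}
#' @export
camera_spec <- function(eye, look_at = c(0, 0, 0), up = c(0, 1, 0),
                        field_of_view = 45,
                        projection = c("perspective", "orthographic")) {
  projection <- match.arg(projection)
  eye <- as.numeric(eye); look_at <- as.numeric(look_at); up <- as.numeric(up)
  fwd <- look_at - eye
  if (sqrt(sum(fwd^2)) < 1e-12) stop("degenerate camera: eye equals look_at")
  cr <- c(fwd[2] * up[3] - fwd[3] * up[2],
          fwd[3] * up[1] - fwd[1] * up[3],
          fwd[1] * up[2] - fwd[2] * up[1])
  if (sqrt(sum(cr^2)) < 1e-12)
    stop("degenerate camera: up parallel to view direction")
  structure(list(eye = eye, look_at = look_at, up = up,
                 field_of_view = field_of_view, projection = projection),
            class = "camera_spec")
}

#' Project 3D positions to image pixels
#'
#' Standard look-at view transform followed by a perspective (or
#' orthographic) projection.  Points at or behind the eye plane are culled
#' and listed in the \code{culled} attribute with a warning.
#'
#' @param layout an \code{nv_layout} (or bare coordinate matrix with
#'   rownames)
#' @param camera a \code{\link{camera_spec}}
#' @param size \code{c(width, height)} in pixels
#' @return data.frame(id, px, py, depth, scale); attribute \code{culled}
#' @export
project_layout <- function(layout, camera, size = c(800, 600)) {
  pos <- unclass(layout)[, 1:3, drop = FALSE]
  w <- size[1]; h <- size[2]
  f <- camera$look_at - camera$eye
  f <- f / sqrt(sum(f^2))
  r <- c(f[2] * camera$up[3] - f[3] * camera$up[2],
         f[3] * camera$up[1] - f[1] * camera$up[3],
         f[1] * camera$up[2] - f[2] * camera$up[1])
  r <- r / sqrt(sum(r^2))
  u <- c(r[2] * f[3] - r[3] * f[2],
         r[3] * f[1] - r[1] * f[3],
         r[1] * f[2] - r[2] * f[1])
  rel <- sweep(pos, 2, camera$eye)
  xc <- rel %*% r; yc <- rel %*% u; zc <- rel %*% f
  focal <- (h / 2) / tan(camera$field_of_view / 2 * pi / 180)
  if (camera$projection == "perspective") {
    culled <- zc <= 1e-9
    s <- ifelse(culled, NA, focal / zc)
  } else {
    d0 <- sqrt(sum((camera$look_at - camera$eye)^2))
    s <- rep(focal / d0, nrow(pos))
    culled <- rep(FALSE, nrow(pos))
  }
  out <- data.frame(id = rownames(pos),
                    px = as.numeric(w / 2 + xc * s),
                    py = as.numeric(h / 2 - yc * s),
                    depth = as.numeric(zc),
                    scale = as.numeric(s),
                    stringsAsFactors = FALSE)
  out$px[culled] <- NA; out$py[culled] <- NA
  if (any(culled))
    warning(sum(culled), " point(s) behind the eye culled", call. = FALSE)
  attr(out, "culled") <- out$id[culled]
  out
}

#' Render style sheet
#' @param background \code{"white"} (print) or \code{"black"} (screen), or
#'   any color
#' @param node_color default node color (hex or name)
#' @param edge_color default edge color
#' @param node_scale world-space glyph radius per unit node size;
#'   \code{NULL} = 2\% of the layout extent
#' @param edge_width edge stroke width in pixels
#' @param bubble_alpha opacity of cluster bubbles (must stay below 1:
#'   bubbles are transparent by design)
#' @param label_color label color; \code{NULL} picks black/white against
#'   the background
#' @export
style_sheet <- function(background = "white", node_color = "#CC2222",
                        edge_color = "#555555", node_scale = NULL,
                        edge_width = 1, bubble_alpha = 0.25,
                        label_color = NULL) {
  stopifnot(bubble_alpha >= 0, bubble_alpha < 1)
  structure(list(background = background, node_color = node_color,
                 edge_color = edge_color, node_scale = node_scale,
                 edge_width = edge_width, bubble_alpha = bubble_alpha,
                 label_color = label_color), class = "style_sheet")
}

.auto_camera <- function(pos) {
  ctr <- if (nrow(pos) > 0) colMeans(pos) else c(0, 0, 0)
  ext <- if (nrow(pos) > 1) max(apply(pos, 2, function(v) diff(range(v))))
  else 1
  ext <- max(ext, 1e-6)
  camera_spec(eye = ctr + c(0, 0, 2.2 * ext + 1), look_at = ctr,
              up = c(0, 1, 0))
}

#' Size-adaptive quality settings
#'
#' Larger networks render with coarser glyphs, fewer polyline segments and
#' smaller layout iteration budgets.  Each setting is a non-increasing step
#' function of n and m.
#'
#' @param n,m node and edge counts
#' @return list(sphere_detail, edge_segments, iteration_budget)
#' @export
adaptive_quality <- function(n, m = 0) {
  stopifnot(n >= 0, m >= 0)
  size <- max(n, m / 4)
  if (size <= 100)        list(sphere_detail = 3L, edge_segments = 32L,
                               iteration_budget = 1000L)
  else if (size <= 1000)  list(sphere_detail = 2L, edge_segments = 16L,
                               iteration_budget = 300L)
  else if (size <= 10000) list(sphere_detail = 1L, edge_segments = 8L,
                               iteration_budget = 60L)
  else                    list(sphere_detail = 0L, edge_segments = 4L,
                               iteration_budget = 50L)
}

# fast vector projection shared by the frame renderer (no data.frame)
.project_fast <- function(pos, camera, size) {
  w <- size[1]; h <- size[2]
  f <- camera$look_at - camera$eye
  f <- f / sqrt(sum(f^2))
  r <- c(f[2] * camera$up[3] - f[3] * camera$up[2],
         f[3] * camera$up[1] - f[1] * camera$up[3],
         f[1] * camera$up[2] - f[2] * camera$up[1])
  r <- r / sqrt(sum(r^2))
  u <- c(r[2] * f[3] - r[3] * f[2], r[3] * f[1] - r[1] * f[3],
         r[1] * f[2] - r[2] * f[1])
  rel <- sweep(pos, 2, camera$eye)
  xc <- drop(rel %*% r); yc <- drop(rel %*% u); zc <- drop(rel %*% f)
  focal <- (h / 2) / tan(camera$field_of_view / 2 * pi / 180)
  if (camera$projection == "perspective") {
    s <- ifelse(zc > 1e-9, focal / zc, NA)
  } else {
    s <- rep(focal / sqrt(sum((camera$look_at - camera$eye)^2)), nrow(pos))
  }
  list(px = w / 2 + xc * s, py = h / 2 - yc * s, depth = zc, scale = s)
}

# sample many segments into pixel coordinates at ~1 px spacing, vectorized
.sample_segments <- function(x0, y0, x1, y1) {
  keep <- is.finite(x0) & is.finite(x1) & is.finite(y0) & is.finite(y1)
  x0 <- x0[keep]; y0 <- y0[keep]; x1 <- x1[keep]; y1 <- y1[keep]
  if (length(x0) == 0) return(list(xs = integer(0), ys = integer(0)))
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ns <- pmax(2L, pmin(ceiling(len) + 1L, 20000L))
  t <- (sequence(ns) - 1) / rep(ns - 1L, ns)
  xs <- rep(x0, ns) + t * rep(x1 - x0, ns)
  ys <- rep(y0, ns) + t * rep(y1 - y0, ns)
  list(xs = round(xs), ys = round(ys))
}

.render_frame <- function(g, pos, camera, style, resolution, bundles = NULL,
                          bubbles = NULL, labels = "none", label_top = 10) {
  w <- resolution[1]; h <- resolution[2]
  bg <- .col01(style$background)
  img <- .canvas(w, h, bg)
  if (nrow(pos) == 0) return(img)
  prf <- .project_fast(pos, camera, resolution)
  pr <- data.frame(id = rownames(pos), px = prf$px, py = prf$py,
                   depth = prf$depth, scale = prf$scale,
                   stringsAsFactors = FALSE)
  rownames(pr) <- pr$id
  ext <- if (nrow(pos) > 1) max(apply(pos, 2, function(v) diff(range(v))))
  else 1
  nscale <- if (is.null(style$node_scale)) 0.02 * max(ext, 1e-6)
  else style$node_scale
  quality <- adaptive_quality(nrow(pos), n_edges(g))

  if (!is.null(bubbles)) {
    bp <- suppressWarnings(project_layout(
      nv_layout(bubbles$centers), camera, resolution))
    ord <- order(-bp$depth)
    for (i in ord) {
      if (is.na(bp$px[i])) next
      img <- .px_disc(img, bp$px[i], bp$py[i],
                      bubbles$radii[i] * bp$scale[i],
                      .col01("#88AACC"), alpha = style$bubble_alpha)
    }
  }

  ecol <- .col01(style$edge_color)
  edges <- g$edges
  seg <- NULL   # segment endpoint pixel coords + per-segment color group
  if (!is.null(bundles)) {
    # downsample each polyline to the quality tier's segment count, stack
    # all points, project once
    sel <- lapply(bundles, function(b) {
      np <- nrow(b$points)
      step <- max(1L, np %/% max(quality$edge_segments, 2L))
      unique(c(seq(1L, np, by = step), np))
    })
    all_pts <- do.call(rbind, lapply(seq_along(bundles), function(i)
      bundles[[i]]$points[sel[[i]], , drop = FALSE]))
    bp <- .project_fast(all_pts, camera, resolution)
    counts <- lengths(sel)
    ends <- cumsum(counts); starts <- ends - counts + 1L
    idx0 <- unlist(lapply(seq_along(counts), function(i)
      starts[i]:(ends[i] - 1L)), use.names = FALSE)
    seg <- list(x0 = bp$px[idx0], y0 = bp$py[idx0],
                x1 = bp$px[idx0 + 1L], y1 = bp$py[idx0 + 1L],
                col = list(ecol), grp = rep(1L, length(idx0)))
  } else if (nrow(edges) > 0) {
    si <- match(edges$source, pr$id); ti <- match(edges$target, pr$id)
    cols <- ifelse(is.na(edges$color), "", edges$color)
    ucol <- unique(cols)
    seg <- list(x0 = pr$px[si], y0 = pr$py[si],
                x1 = pr$px[ti], y1 = pr$py[ti],
                col = lapply(ucol, function(cc)
                  if (cc == "") ecol else .col01(cc)),
                grp = match(cols, ucol))
  }
  if (!is.null(seg)) {
    for (gi in seq_along(seg$col)) {
      w_i <- seg$grp == gi
      sp <- .sample_segments(seg$x0[w_i], seg$y0[w_i],
                             seg$x1[w_i], seg$y1[w_i])
      if (style$edge_width > 1.5) {
        r <- style$edge_width / 2
        off <- expand.grid(dx = -ceiling(r):ceiling(r),
                           dy = -ceiling(r):ceiling(r))
        off <- off[off$dx^2 + off$dy^2 <= r^2, ]
        sp <- list(xs = as.vector(outer(sp$xs, off$dx, "+")),
                   ys = as.vector(outer(sp$ys, off$dy, "+")))
      }
      keep <- !duplicated(cbind(sp$xs, sp$ys))
      img <- .blend_px(img, sp$ys[keep], sp$xs[keep], seg$col[[gi]], 1)
    }
    # arrowheads near the target of directed edges
    if (is.null(bundles) && any(edges$directed %in% TRUE)) {
      di <- which(edges$directed %in% TRUE)
      for (i in di) {
        a <- pr[edges$source[i], ]; b <- pr[edges$target[i], ]
        if (anyNA(c(a$px, b$px))) next
        col <- if (!is.na(edges$color[i])) .col01(edges$color[i]) else ecol
        t <- 0.88
        img <- .px_disc(img, a$px + t * (b$px - a$px),
                        a$py + t * (b$py - a$py),
                        1.5 * style$edge_width + 1, col)
      }
    }
  }

  nd <- g$nodes
  ni <- match(nd$id, pr$id)
  npx <- pr$px[ni]; npy <- pr$py[ni]; nsc <- pr$scale[ni]
  ncolv <- ifelse(is.na(nd$color), style$node_color, nd$color)
  ord <- order(-pr$depth[ni])   # painter's order, far first
  shade <- quality$sphere_detail >= 1
  for (i in ord) {
    if (is.na(npx[i])) next
    img <- .px_disc(img, npx[i], npy[i], nscale * nd$size[i] * nsc[i],
                    .col01(ncolv[i]), shade = shade)
  }

  if (!identical(labels, "none") && nrow(nd) > 0) {
    lab_ids <- if (identical(labels, "all")) nd$id else {
      deg <- node_degrees(g)
      names(sort(deg, decreasing = TRUE))[seq_len(min(label_top, nrow(nd)))]
    }
    fg <- if (is.null(style$label_color)) {
      if (mean(bg) > 0.5) c(0, 0, 0) else c(1, 1, 1)
    } else .col01(style$label_color)
    halo <- if (mean(fg) > 0.5) c(0, 0, 0) else c(1, 1, 1)
    for (id in lab_ids) {
      p <- pr[id, ]
      if (is.na(p$px)) next
      nm <- nd$name[nd$id == id][1]
      img <- .px_text(img, p$px + 4, p$py - 4, nm, fg, halo)
    }
  }
  img
}

#' Render a PNG snapshot
#'
#' Depth-sorted painter's rendering of a layout (optionally with bundled
#' edges and cluster bubbles) to a PNG file.  Output bytes are a pure
#' function of the inputs.
#'
#' @param g an \code{nv_graph}
#' @param layout an \code{nv_layout} covering the graph
#' @param path output PNG path
#' @param camera a \code{\link{camera_spec}}; \code{NULL} = auto-framed
#' @param style a \code{\link{style_sheet}}
#' @param resolution \code{c(width, height)}, at most 20000 px per side
#' @param bundles optional result of \code{\link{bundle_edges}}
#' @param bubbles optional result of \code{\link{layout_cluster_bubbles}}
#'   or \code{\link{layout_circos3d}}
#' @param labels \code{"none"}, \code{"all"} or \code{"top"}
#' @param label_top how many highest-degree nodes to label for
#'   \code{labels = "top"}
#' @export
render_snapshot <- function(g, layout, path, camera = NULL,
                            style = style_sheet(),
                            resolution = c(800, 600), bundles = NULL,
                            bubbles = NULL, labels = "none",
                            label_top = 10) {
  if (any(resolution < 1)) stop("image size must be positive")
  if (any(resolution > 20000)) stop("at most 20000 px per side")
  pos <- unclass(layout)[, 1:3, drop = FALSE]
  if (is.null(camera)) camera <- .auto_camera(pos)
  img <- .render_frame(g, pos, camera, style, resolution, bundles, bubbles,
                       labels, label_top)
  png::writePNG(img, path)
  invisible(path)
}

.rotate_about <- function(pos, axis, angle, center) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  Rm <- diag(3) * ca + sa * K + (1 - ca) * outer(a, a)
  sweep(sweep(pos, 2, center) %*% t(Rm), 2, center, "+")
}

#' Render a rotating-network GIF movie
#'
#' Frame f (0-based) shows the layout rotated by
#' \code{f * degrees_total / n_frames} about the given axis through the
#' layout centroid, so a 360-degree movie loops seamlessly.
#'
#' @inheritParams render_snapshot
#' @param axis rotation axis (3-vector)
#' @param n_frames number of frames (>= 2)
#' @param degrees_total total rotation across the movie
#' @param delay_cs per-frame delay in hundredths of a second
#' @export
render_rotation <- function(g, layout, path, axis = c(0, 1, 0),
                            n_frames = 18, degrees_total = 360,
                            camera = NULL, style = style_sheet(),
                            resolution = c(400, 300), delay_cs = 10,
                            labels = "none") {
  if (n_frames < 2) stop("need at least 2 frames")
  pos <- unclass(layout)[, 1:3, drop = FALSE]
  center <- if (nrow(pos) > 0) colMeans(pos) else c(0, 0, 0)
  if (is.null(camera)) camera <- .auto_camera(pos)
  frames <- lapply(seq_len(n_frames) - 1L, function(f) {
    ang <- f * degrees_total / n_frames * pi / 180
    rpos <- if (nrow(pos) > 0) .rotate_about(pos, axis, ang, center) else pos
    rownames(rpos) <- rownames(pos)
    .render_frame(g, rpos, camera, style, resolution, labels = labels)
  })
  .write_gif(frames, path, delay_cs)
  invisible(path)
}
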
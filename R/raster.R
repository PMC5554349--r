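# Minimal deterministic software rasterizer.  Images are h x w x 3 arrays in
# [0,1]; drawing is plain array arithmetic so identical inputs give
# byte-identical PNG/GIF output across runs.

.canvas <- function(w, h, bg = c(1, 1, 1)) {
  img <- array(0, c(h, w, 3))
  img[, , 1] <- bg[1]; img[, , 2] <- bg[2]; img[, , 3] <- bg[3]
  img
}

.col01 <- function(col) {
  if (is.character(col)) as.numeric(grDevices::col2rgb(col)) / 255
  else as.numeric(col)
}

# alpha-blend color into the pixels given by an index matrix (row, col)
.blend_px <- function(img, rows, cols, col, alpha = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  if (!any(ok)) return(img)
  rows <- rows[ok]; cols <- cols[ok]
  for (c in 1:3) {
    idx <- cbind(rows, cols, c)
    img[idx] <- (1 - alpha) * img[idx] + alpha * col[c]
  }
  img
}

# filled disc; shade = simple spherical highlight (brighter towards the
# upper-left of the glyph) so node glyphs read as spheres
.px_disc <- function(img, cx, cy, r, col, alpha = 1, shade = FALSE) {
  if (!is.finite(cx) || !is.finite(cy) || r <= 0) return(img)
  r <- max(r, 0.75)
  xs <- floor(cx - r):ceiling(cx + r)
  ys <- floor(cy - r):ceiling(cy + r)
  gg <- expand.grid(x = xs, y = ys)
  d2 <- (gg$x - cx)^2 + (gg$y - cy)^2
  inside <- d2 <= r^2
  if (!any(inside)) return(img)
  gx <- gg$x[inside]; gy <- gg$y[inside]; d2 <- d2[inside]
  if (shade) {
    hx <- cx - 0.35 * r; hy <- cy - 0.35 * r
    f <- 1 - 0.55 * sqrt(((gx - hx)^2 + (gy - hy)^2)) / (2 * r)
    h <- dim(img)[1]; w <- dim(img)[2]
    ok <- gy >= 1 & gy <= h & gx >= 1 & gx <= w
    gx <- gx[ok]; gy <- gy[ok]; f <- f[ok]
    for (c in 1:3) {
      idx <- cbind(gy, gx, c)
      img[idx] <- (1 - alpha) * img[idx] + alpha * pmin(1, col[c] * f + 0.15 * f)
    }
    img
  } else {
    .blend_px(img, gy, gx, col, alpha)
  }
}

.px_line <- function(img, x0, y0, x1, y1, col, width = 1, alpha = 1) {
  if (any(!is.finite(c(x0, y0, x1, y1)))) return(img)
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ns <- max(2L, ceiling(len) + 1L)
  t <- seq(0, 1, length.out = ns)
  xs <- round(x0 + t * (x1 - x0)); ys <- round(y0 + t * (y1 - y0))
  if (width <= 1.5) {
    keep <- !duplicated(cbind(xs, ys))
    .blend_px(img, ys[keep], xs[keep], col, alpha)
  } else {
    r <- width / 2
    off <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    px <- outer(xs, off$dx, "+"); py <- outer(ys, off$dy, "+")
    keep <- !duplicated(cbind(as.vector(px), as.vector(py)))
    .blend_px(img, as.vector(py)[keep], as.vector(px)[keep], col, alpha)
  }
}

.px_polyline <- function(img, xs, ys, col, width = 1, alpha = 1) {
  for (i in seq_len(length(xs) - 1))
    img <- .px_line(img, xs[i], ys[i], xs[i + 1], ys[i + 1], col, width,
                    alpha)
  img
}

# ---- 5x7 bitmap font (uppercase, digits, basic punctuation) --------------

.font5x7 <- local({
  def <- list(
    "0" = c("01110","10001","10011","10101","11001","10001","01110"),
    "1" = c("00100","01100","00100","00100","00100","00100","01110"),
    "2" = c("01110","10001","00001","00110","01000","10000","11111"),
    "3" = c("11110","00001","00001","01110","00001","00001","11110"),
    "4" = c("00010","00110","01010","10010","11111","00010","00010"),
    "5" = c("11111","10000","11110","00001","00001","10001","01110"),
    "6" = c("01110","10000","10000","11110","10001","10001","01110"),
    "7" = c("11111","00001","00010","00100","01000","01000","01000"),
    "8" = c("01110","10001","10001","01110","10001","10001","01110"),
    "9" = c("01110","10001","10001","01111","00001","00001","01110"),
    "A" = c("01110","10001","10001","11111","10001","10001","10001"),
    "B" = c("11110","10001","10001","11110","10001","10001","11110"),
    "C" = c("01110","10001","10000","10000","10000","10001","01110"),
    "D" = c("11110","10001","10001","10001","10001","10001","11110"),
    "E" = c("11111","10000","10000","11110","10000","10000","11111"),
    "F" = c("11111","10000","10000","11110","10000","10000","10000"),
    "G" = c("01110","10001","10000","10111","10001","10001","01111"),
    "H" = c("10001","10001","10001","11111","10001","10001","10001"),
    "I" = c("01110","00100","00100","00100","00100","00100","01110"),
    "J" = c("00111","00010","00010","00010","00010","10010","01100"),
    "K" = c("10001","10010","10100","11000","10100","10010","10001"),
    "L" = c("10000","10000","10000","10000","10000","10000","11111"),
    "M" = c("10001","11011","10101","10101","10001","10001","10001"),
    "N" = c("10001","11001","10101","10011","10001","10001","10001"),
    "O" = c("01110","10001","10001","10001","10001","10001","01110"),
    "P" = c("11110","10001","10001","11110","10000","10000","10000"),
    "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
    "R" = c("11110","10001","10001","11110","10100","10010","10001"),
    "S" = c("01111","10000","10000","01110","00001","00001","11110"),
    "T" = c("11111","00100","00100","00100","00100","00100","00100"),
    "U" = c("10001","10001","10001","10001","10001","10001","01110"),
    "V" = c("10001","10001","10001","10001","10001","01010","00100"),
    "W" = c("10001","10001","10001","10101","10101","11011","10001"),
    "X" = c("10001","01010","00100","00100","00100","01010","10001"),
    "Y" = c("10001","01010","00100","00100","00100","00100","00100"),
    "Z" = c("11111","00001","00010","00100","01000","10000","11111"),
    "." = c("00000","00000","00000","00000","00000","01100","01100"),
    "-" = c("00000","00000","00000","11111","00000","00000","00000"),
    "_" = c("00000","00000","00000","00000","00000","00000","11111"),
    ":" = c("00000","01100","01100","00000","01100","01100","00000"),
    "/" = c("00001","00010","00100","00100","01000","10000","00000"),
    "(" = c("00010","00100","01000","01000","01000","00100","00010"),
    ")" = c("01000","00100","00010","00010","00010","00100","01000"),
    "," = c("00000","00000","00000","00000","01100","00100","01000"),
    " " = c("00000","00000","00000","00000","00000","00000","00000"))
  lapply(def, function(rows)
    do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]] == "1"))))
})

.px_text <- function(img, x, y, text, col, halo = NULL) {
  text <- toupper(as.character(text))
  chars <- strsplit(text, "")[[1]]
  cx <- round(x)
  for (ch in chars) {
    glyph <- .font5x7[[ch]]
    if (is.null(glyph)) glyph <- .font5x7[["."]]
    on <- which(glyph == 1, arr.ind = TRUE)
    if (nrow(on) > 0) {
      rows <- round(y) - 7 + on[, 1]
      cols <- cx + on[, 2] - 1
      if (!is.null(halo))
        for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0)))
          img <- .blend_px(img, rows + d[1], cols + d[2], halo, 1)
      img <- .blend_px(img, rows, cols, col, 1)
    }
    cx <- cx + 6
  }
  img
}

# simple deterministic bar chart used for the statistics distributions
.plot_bars <- function(x, y, xlab, path, w = 600, h = 400) {
  img <- .canvas(w, h, c(1, 1, 1))
  fg <- c(0, 0, 0); bar <- .col01("#4878A8")
  ml <- 60; mr <- 20; mt <- 20; mb <- 50
  img <- .px_line(img, ml, h - mb, w - mr, h - mb, fg)
  img <- .px_line(img, ml, mt, ml, h - mb, fg)
  if (length(x) > 0 && any(is.finite(y))) {
    ymax <- max(y[is.finite(y)], 1e-12)
    nb <- length(x)
    bw <- max(1, floor((w - ml - mr) / max(nb, 1) * 0.8))
    for (i in seq_len(nb)) {
      if (!is.finite(y[i])) next
      x0 <- ml + (i - 0.5) / nb * (w - ml - mr) - bw / 2
      hh <- (h - mb - mt) * y[i] / ymax
      for (xx in round(x0):round(x0 + bw))
        img <- .px_line(img, xx, h - mb - 1, xx, h - mb - hh, bar)
    }
    img <- .px_text(img, ml - 50, mt + 8, format(signif(ymax, 3)), fg)
    step <- max(1L, ceiling(nb / 10))
    for (i in seq(1, nb, by = step))
      img <- .px_text(img, ml + (i - 0.5) / nb * (w - ml - mr) - 5,
                      h - mb + 12, format(x[i]), fg)
  }
  img <- .px_text(img, (w - 6 * nchar(xlab)) / 2, h - 15, xlab, fg)
  png::writePNG(img, path)
  invisible(path)
}
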
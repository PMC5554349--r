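# GIF89a writer for rotation movies.  A global 256-color palette is adapted
# from the first frame (its exact colors when few enough, otherwise a fixed
# 6x7x6 RGB cube); pixel streams are LZW-coded with fixed-width 9-bit
# literal codes and periodic clear codes, which every decoder accepts and
# keeps the encoder simple and byte-deterministic.

# pixels of a frame in GIF raster order (left-to-right, top-to-bottom)
.frame_px <- function(frame) {
  cbind(as.vector(t(frame[, , 1])),
        as.vector(t(frame[, , 2])),
        as.vector(t(frame[, , 3])))
}

.gif_palette <- function(frame) {
  px <- round(pmin(pmax(.frame_px(frame), 0), 1) * 255)
  cols <- unique(matrix(as.integer(px), ncol = 3, dimnames = NULL))
  if (nrow(cols) <= 256) return(cols)
  # 6 x 7 x 6 uniform cube (252 entries)
  grid <- expand.grid(r = round(seq(0, 255, length.out = 6)),
                      g = round(seq(0, 255, length.out = 7)),
                      b = round(seq(0, 255, length.out = 6)))
  as.matrix(grid)
}

.gif_index_frame <- function(frame, palette) {
  px <- matrix(as.integer(round(pmin(pmax(.frame_px(frame), 0), 1) * 255)),
               ncol = 3)
  if (nrow(palette) == 252) {  # the uniform cube: direct arithmetic index
    r <- pmin(5L, as.integer(round(px[, 1] / 255 * 5)))
    g <- pmin(6L, as.integer(round(px[, 2] / 255 * 6)))
    b <- pmin(5L, as.integer(round(px[, 3] / 255 * 5)))
    return(b * 42L + g * 6L + r)
  }
  key <- px[, 1] * 65536L + px[, 2] * 256L + px[, 3]
  pkey <- palette[, 1] * 65536L + palette[, 2] * 256L + palette[, 3]
  idx <- match(key, pkey)
  miss <- which(is.na(idx))
  for (i in miss)  # nearest palette color for colors absent from frame 1
    idx[i] <- which.min((palette[, 1] - px[i, 1])^2 +
                        (palette[, 2] - px[i, 2])^2 +
                        (palette[, 3] - px[i, 3])^2)
  idx - 1L
}

# LZW stream of 9-bit literals: CLEAR, then pixel codes with a CLEAR
# re-emitted before the decoder's dictionary would outgrow 9 bits, EOI last.
.gif_lzw <- function(indices) {
  clear <- 256L; eoi <- 257L
  span <- 253L   # dictionary grows by one per emitted code; 511 - 258 = 253
  chunks <- split(indices, (seq_along(indices) - 1) %/% span)
  codes <- c(unlist(lapply(chunks, function(ch) c(clear, ch)),
                    use.names = FALSE), eoi)
  nb <- length(codes) * 9L
  bits <- integer(nb)
  for (b in 0:8)
    bits[seq_along(codes) * 9L - 8L + b] <-
      bitwAnd(bitwShiftR(codes, b), 1L)
  if (nb %% 8 != 0) bits <- c(bits, integer(8 - nb %% 8))
  bytes <- as.raw(colSums(matrix(bits, nrow = 8) * 2^(0:7)))
  bytes
}

.gif_subblocks <- function(bytes) {
  out <- raw(0)
  i <- 1L
  while (i <= length(bytes)) {
    j <- min(i + 254L, length(bytes))
    out <- c(out, as.raw(j - i + 1L), bytes[i:j])
    i <- j + 1L
  }
  c(out, as.raw(0L))
}

.u16 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8)))

.write_gif <- function(frames, path, delay_cs = 10) {
  stopifnot(length(frames) >= 1)
  h <- dim(frames[[1]])[1]; w <- dim(frames[[1]])[2]
  pal <- .gif_palette(frames[[1]])
  gct <- matrix(0L, 256, 3)
  gct[seq_len(nrow(pal)), ] <- pal
  out <- c(charToRaw("GIF89a"),
           .u16(w), .u16(h), as.raw(0xF7), as.raw(0), as.raw(0),
           as.raw(as.integer(t(gct))),
           # application extension: loop forever
           as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
           as.raw(c(0x03, 0x01, 0x00, 0x00, 0x00)))
  for (f in frames) {
    idx <- .gif_index_frame(f, pal)
    out <- c(out,
             as.raw(c(0x21, 0xF9, 0x04, 0x00)), .u16(delay_cs),
             as.raw(c(0x00, 0x00)),
             as.raw(0x2C), .u16(0L), .u16(0L), .u16(w), .u16(h), as.raw(0),
             as.raw(8), .gif_subblocks(.gif_lzw(idx)))
  }
  out <- c(out, as.raw(0x3B))
  writeBin(out, path)
  invisible(path)
}
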
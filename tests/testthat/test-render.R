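test_that("projection maps the look-at point to the image center and culls", {
  cam <- camera_spec(eye = c(0, 0, 10), look_at = c(0, 0, 0))
  pos <- rbind(center = c(0, 0, 0), off = c(1, 0, 0),
               behind = c(0, 0, 20))
  expect_warning(pr <- project_layout(nv_layout(pos), cam, c(200, 100)),
                 "culled")
  expect_equal(pr$px[1], 100); expect_equal(pr$py[1], 50)
  expect_true(is.na(pr$px[3]))
  expect_equal(attr(pr, "culled"), "behind")

  ortho <- camera_spec(eye = c(0, 0, 10), look_at = c(0, 0, 0),
                       projection = "orthographic")
  pos2 <- rbind(a = c(1, 1, 0), b = c(1, 1, -5))
  pr2 <- project_layout(nv_layout(pos2), ortho, c(200, 100))
  expect_equal(pr2$px[1], pr2$px[2])
  expect_equal(pr2$py[1], pr2$py[2])

  expect_error(camera_spec(eye = c(0, 0, 0), look_at = c(0, 0, 0)),
               "degenerate")
  expect_error(camera_spec(eye = c(0, 0, 1), look_at = c(0, 0, 0),
                           up = c(0, 0, 1)), "parallel")
})

test_that("snapshots are deterministic, colored and bounded", {
  d <- withr::local_tempdir()
  g <- nv_graph(data.frame(source = "a", target = "b"),
                data.frame(id = c("a", "b"), color = c("#FF0000", NA)))
  l <- layout_force_directed(g, fr_params(seed = 1, iterations = 50))
  f1 <- file.path(d, "a.png"); f2 <- file.path(d, "b.png")
  render_snapshot(g, l, f1, resolution = c(120, 90))
  render_snapshot(g, l, f2, resolution = c(120, 90))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  img <- png::readPNG(f1)
  expect_equal(dim(img)[1:2], c(90, 120))
  # a red node glyph leaves red-dominant pixels somewhere
  expect_true(any(img[, , 1] > 0.5 & img[, , 2] < 0.4))

  # empty graph renders the bare background
  fe <- file.path(d, "empty.png")
  render_snapshot(nv_graph(), nv_layout(matrix(0, 0, 3)), fe,
                  resolution = c(40, 30),
                  style = style_sheet(background = "black"))
  em <- png::readPNG(fe)
  expect_true(all(em == 0))

  expect_error(render_snapshot(g, l, f1, resolution = c(0, 10)), "positive")
  expect_error(render_snapshot(g, l, f1, resolution = c(30000, 10)),
               "20000")
})

test_that("bubbles render translucently (background shows through)", {
  g <- make_clique(4)
  p <- nv_partition(stats::setNames(rep(0L, 4), node_ids(g)))
  bl <- layout_cluster_bubbles(g, p)
  d <- withr::local_tempdir()
  f <- file.path(d, "bub.png")
  # node glyphs shrunk to nothing so sampled pixels show bubble over bg
  render_snapshot(g, bl$node_positions, f, bubbles = bl,
                  resolution = c(120, 90),
                  style = style_sheet(node_scale = 1e-6))
  img <- png::readPNG(f)
  mixed <- img[, , 3] < 1 & img[, , 3] > 0.5
  expect_true(any(mixed))   # neither pure white bg nor opaque bubble color
})

test_that("rotation movies have exact frame counts and wrap around", {
  g <- make_path(3)
  l <- layout_force_directed(g, fr_params(seed = 2, iterations = 50))
  d <- withr::local_tempdir()
  f <- file.path(d, "rot.gif")
  render_rotation(g, l, f, n_frames = 4, degrees_total = 360,
                  resolution = c(60, 40))
  bytes <- readBin(f, "raw", file.size(f))
  expect_equal(rawToChar(bytes[1:6]), "GIF89a")
  # image descriptors: 0x2C separators at block boundaries; count frames by
  # graphic control extensions 21 F9
  gce <- sum(bytes[-length(bytes)] == as.raw(0x21) &
             bytes[-1] == as.raw(0xF9))
  expect_equal(gce, 4)

  # 0 degrees total: every frame renders identically, so the GIF equals a
  # repeated-frame movie of frame 0
  f0 <- file.path(d, "still.gif")
  render_rotation(g, l, f0, n_frames = 3, degrees_total = 0,
                  resolution = c(60, 40))
  b0 <- readBin(f0, "raw", file.size(f0))
  # frames are identical blocks; compare the two image data segments
  seps <- which(b0 == as.raw(0x2C))
  expect_gte(length(seps), 3)

  # wrap-around: rotating by 360 reproduces frame 0 exactly
  fr0 <- netvis3d:::.render_frame(g, unclass(l), netvis3d:::.auto_camera(unclass(l)),
                                  style_sheet(), c(60, 40))
  rot <- netvis3d:::.rotate_about(unclass(l), c(0, 1, 0), 2 * pi,
                                  colMeans(unclass(l)))
  rownames(rot) <- rownames(unclass(l))
  fr360 <- netvis3d:::.render_frame(g, rot, netvis3d:::.auto_camera(unclass(l)),
                                    style_sheet(), c(60, 40))
  expect_equal(fr0, fr360, tolerance = 1e-12)

  # asymmetric layouts change under half rotation
  rot180 <- netvis3d:::.rotate_about(unclass(l), c(0, 1, 0), pi,
                                     colMeans(unclass(l)))
  rownames(rot180) <- rownames(unclass(l))
  fr180 <- netvis3d:::.render_frame(g, rot180,
                                    netvis3d:::.auto_camera(unclass(l)),
                                    style_sheet(), c(60, 40))
  expect_false(isTRUE(all.equal(fr0, fr180)))

  expect_error(render_rotation(g, l, f, n_frames = 1), "2 frames")
})

test_that("rendering does not mutate the layout", {
  g <- make_cycle(5)
  l <- layout_force_directed(g, fr_params(seed = 3, iterations = 40))
  before <- unclass(l)[, 1:3]
  d <- withr::local_tempdir()
  render_snapshot(g, l, file.path(d, "x.png"), resolution = c(50, 50),
                  labels = "all")
  expect_identical(unclass(l)[, 1:3], before)
})

test_that("adaptive quality is a non-increasing step function of size", {
  top <- adaptive_quality(10)
  bottom <- adaptive_quality(1e6)
  expect_equal(top$sphere_detail, 3L)
  expect_equal(bottom$sphere_detail, 0L)
  sizes <- c(10, 99, 100, 500, 1000, 5000, 10000, 1e5, 1e6)
  qs <- lapply(sizes, adaptive_quality)
  for (f in c("sphere_detail", "edge_segments")) {
    v <- vapply(qs, `[[`, integer(1), f)
    expect_true(all(diff(v) <= 0))
  }
  v <- vapply(qs, `[[`, integer(1), "iteration_budget")
  expect_true(all(diff(v) <= 0))
})
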
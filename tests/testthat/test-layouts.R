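# The FR equilibrium length for the default volume of 1000
k_for <- function(n, volume = 1000) (volume / n)^(1 / 3)

test_that("FR force pair follows the printed forms and k from the cube root", {
  k <- 1
  expect_equal(fr_forces(2, 1), c(attractive = 4, repulsive = -0.5))
  expect_equal(unname(fr_forces(3, 3)[1]), -unname(fr_forces(3, 3)[2]))
  expect_equal(k_for(1, volume = 8), 2)
  expect_error(fr_forces(0, 1))
})

test_that("force-directed layout reaches the pairwise equilibrium", {
  g1 <- nv_graph(nodes = data.frame(id = "solo"))
  l1 <- layout_force_directed(g1)
  expect_equal(unname(unclass(l1)[1, ]), c(0, 0, 0))

  g2 <- nv_graph(data.frame(source = "a", target = "b"))
  l2 <- layout_force_directed(g2, fr_params(seed = 1))
  d <- as.numeric(dist(unclass(l2)))
  expect_lt(abs(d - k_for(2)) / k_for(2), 0.10)

  st <- attr(l2, "stress")
  expect_lte(st["final"], st["initial"])
})

test_that("disjoint cliques end up internally tight and mutually separated", {
  mk <- make_modular(2, 5, 1, 0, seed = 2)
  l <- layout_force_directed(mk$graph, fr_params(seed = 3))
  pos <- unclass(l)
  mem <- mk$partition$membership[rownames(pos)]
  a <- rownames(pos)[mem == 0]; b <- rownames(pos)[mem == 1]
  intra <- mean(c(dist(pos[a, ]), dist(pos[b, ])))
  inter <- mean(as.matrix(dist(pos))[a, b])
  expect_lt(intra, inter)
  side <- 1000^(1 / 3)
  expect_true(all(abs(sweep(pos, 2, colMeans(pos))) <= side / 2 + 1e-9))
})

test_that("lin-log energy matches an independent double-loop oracle", {
  g <- make_path(3)
  set.seed(5)
  pos <- matrix(rnorm(9), 3, 3, dimnames = list(node_ids(g), NULL))
  for (mode in c("node", "edge")) {
    for (r in c(1, 2, 3)) {
      mine <- linlog_energy(nv_layout(pos), g, linlog_params(r = r, mode = mode))
      ref <- oracle_linlog_energy(pos, g, r, mode)
      expect_equal(mine, ref, tolerance = 1e-9)
    }
  }
  expect_equal(
    linlog_energy(nv_layout(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE,
                                   dimnames = list(c("a", "b")))),
                  nv_graph(data.frame(source = "a", target = "b")),
                  linlog_params(r = 1)), 1)
  expect_error(
    linlog_energy(nv_layout(matrix(0, 2, 3, dimnames = list(c("a", "b")))),
                  nv_graph(data.frame(source = "a", target = "b"))),
    "coincident")
})

test_that("lin-log layouts hit the closed-form single-edge minimizers", {
  g <- nv_graph(data.frame(source = "a", target = "b"))
  # r = 1: d - ln d minimal at d = 1; r = 3: d^3/3 - ln d minimal at d = 1
  for (r in c(1, 3)) {
    l <- layout_linlog(g, linlog_params(r = r, iterations = 600, seed = 2))
    expect_lt(abs(as.numeric(dist(unclass(l))) - 1), 0.05)
  }
})

test_that("lin-log separates clusters and r=3 matches FR distance structure", {
  mk <- make_modular(2, 4, 1, 0, seed = 1)
  l <- layout_linlog(mk$graph, linlog_params(r = 1, iterations = 600,
                                             seed = 4))
  pos <- unclass(l)
  mem <- mk$partition$membership[rownames(pos)]
  a <- rownames(pos)[mem == 0]; b <- rownames(pos)[mem == 1]
  expect_lt(mean(c(dist(pos[a, ]), dist(pos[b, ]))),
            mean(as.matrix(dist(pos))[a, b]))

  tri <- make_cycle(3)
  l3 <- layout_linlog(tri, linlog_params(r = 3, iterations = 800, seed = 1))
  lfr <- layout_force_directed(tri, fr_params(volume = 3, seed = 1,
                                              iterations = 800))
  d3 <- sort(as.numeric(dist(unclass(l3))))
  dfr <- sort(as.numeric(dist(unclass(lfr))))
  expect_lt(max(abs(d3 - dfr) / dfr), 0.10)
})

test_that("lin-log optimizer energy is non-increasing over accepted steps", {
  g <- make_scale_free(12, 2, seed = 3)
  p <- linlog_params(r = 1, iterations = 50, seed = 1)
  energies <- vapply(c(10, 25, 50), function(it)
    attr(layout_linlog(g, linlog_params(r = 1, iterations = it, seed = 1)),
         "energy"), numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("spectral bisection agrees with the dense Fiedler oracle", {
  pg <- make_path(4)
  b <- spectral_bisect(pg)
  parts <- lapply(b$parts, sort)
  expect_true(setequal(parts[[1]], c("n001", "n002")) ||
              setequal(parts[[1]], c("n003", "n004")))
  expect_equal(sort(unname(b$q[c("n001", "n002")])),
               -sort(unname(b$q[c("n004", "n003")])))

  or <- oracle_fiedler_space(pg)
  expect_lt(abs(b$lambda - or$lambda), 1e-8)

  # barbell: the bisection cuts exactly the bridge (brute-force oracle)
  bb <- make_barbell(3)
  sb <- spectral_bisect(bb)
  mc <- oracle_min_balanced_cut(bb)
  expect_true(setequal(sb$parts$A, mc$parts[[1]]) ||
              setequal(sb$parts$A, mc$parts[[2]]))

  e2 <- nv_graph(nodes = data.frame(id = c("x", "y")))
  expect_error(spectral_bisect(e2), "disconnected")
})

test_that("power iteration matches dense eigenvectors on random small graphs", {
  for (seed in 1:25) {
    g <- random_small_graph(seed, nmax = 10)
    b <- spectral_bisect(g)
    or <- oracle_fiedler_space(g)
    v <- b$fiedler[node_ids(g)]
    proj <- or$space %*% crossprod(or$space, v)
    cosine <- sqrt(sum(proj^2)) / sqrt(sum(v^2))
    expect_gt(cosine, 0.999)
  }
})

test_that("hybrid layout separates the parts into disjoint boxes", {
  g <- make_path(4)
  l <- layout_hybrid(g, fr_params(seed = 1))
  parts <- attr(l, "parts")
  expect_length(parts, 2)
  pos <- unclass(l)
  r1 <- apply(pos[parts[[1]], , drop = FALSE], 2, range)
  r2 <- apply(pos[parts[[2]], , drop = FALSE], 2, range)
  overlap <- all(r1[1, ] <= r2[2, ] & r2[1, ] <= r1[2, ])
  expect_false(overlap)

  g1 <- nv_graph(nodes = data.frame(id = "only"))
  expect_equal(unname(unclass(layout_hybrid(g1))[1, ]), c(0, 0, 0))

  bb <- make_barbell(3)
  lb <- layout_hybrid(bb, fr_params(seed = 2))
  pb <- attr(lb, "parts")
  expect_true(setequal(pb[[1]], c("a001", "a002", "a003")) ||
              setequal(pb[[1]], c("b001", "b002", "b003")))
})

test_that("coarsening obeys the stop rules and composes projection maps", {
  tri <- make_cycle(3)
  lv <- coarsen(tri)
  expect_length(lv, 1)   # already at min_size

  pg <- make_path(8)
  lv2 <- coarsen(pg, coarsen_params(seed = 1))
  sizes <- vapply(lv2, function(l) n_nodes(l$graph), integer(1))
  expect_true(all(diff(sizes) < 0))
  expect_true(n_nodes(lv2[[length(lv2)]]$graph) <= 3 ||
              sizes[length(sizes)] / sizes[length(sizes) - 1] > 0.75)
  # composed maps cover every original node
  ids <- node_ids(pg)
  for (lev in seq_along(lv2)[-1]) ids <- unname(lv2[[lev]]$map[ids])
  expect_true(all(ids %in% node_ids(lv2[[length(lv2)]]$graph)))

  # star: the hub can merge with only one leaf per round, so one round
  # shrinks K1,5 by exactly one node and the rate rule (5/6 > 0.75) stops it
  st <- make_star(6)
  lv3 <- coarsen(st, coarsen_params(seed = 2))
  expect_length(lv3, 1)
})

test_that("coarsened layout degenerates to FR below min_size and stays close above", {
  tri <- make_cycle(3)
  p <- fr_params(seed = 3, iterations = 200)
  expect_equal(unclass(layout_coarsened(tri, coarsen_params(), p)),
               unclass(layout_force_directed(tri, p)))

  mk <- make_modular(2, 6, 1, 0, seed = 1)
  l <- layout_coarsened(mk$graph, coarsen_params(seed = 1),
                        fr_params(seed = 2, iterations = 200))
  pos <- unclass(l)
  mem <- mk$partition$membership[rownames(pos)]
  a <- rownames(pos)[mem == 0]; b <- rownames(pos)[mem == 1]
  expect_lt(mean(c(dist(pos[a, ]), dist(pos[b, ]))),
            mean(as.matrix(dist(pos))[a, b]))
})

test_that("coarsened FR stress stays within 2x of direct FR on a modular graph", {
  mk <- make_modular(4, 50, 0.25, 0.01, seed = 6)
  g <- mk$graph
  p <- fr_params(seed = 4, iterations = 150)
  stress_of <- function(l) {
    pos <- unclass(l)[node_ids(g), ]
    k <- k_for(n_nodes(g))
    disp <- netvis3d:::fr_displacement(pos, netvis3d:::.edge_index(g), k,
                                       rep(1, n_edges(g)))
    sum(sqrt(rowSums(disp^2)))
  }
  s_direct <- stress_of(layout_force_directed(g, p))
  s_coarse <- stress_of(layout_coarsened(g, coarsen_params(seed = 1), p))
  expect_lt(s_coarse, 2 * s_direct)
})

test_that("annealed layout: edge_cut 0 is exactly FR; cutting separates cliques", {
  tri <- make_cycle(3)
  l0 <- layout_annealed(tri, anneal_schedule(edge_cut = 0, iterations = 150,
                                             seed = 5))
  lf <- layout_force_directed(tri, fr_params(seed = 5, iterations = 150))
  expect_equal(layout_coords(l0), layout_coords(lf))

  expect_error(anneal_schedule(edge_cut = 1.2), "edge_cut")
  le <- layout_annealed(nv_graph(), anneal_schedule())
  expect_equal(nrow(unclass(le)), 0)

  mk <- make_modular(2, 8, 1, 0, seed = 1)$graph
  e <- rbind(mk$edges,
             data.frame(source = "n001", target = "n009", weight = 1,
                        directed = FALSE, color = NA, pattern = NA))
  gb <- nv_graph(e)
  rat <- function(l) {
    pos <- unclass(l)
    a <- rownames(pos)[as.integer(substring(rownames(pos), 2)) <= 8]
    b <- setdiff(rownames(pos), a)
    inter <- sqrt(sum((colMeans(pos[a, ]) - colMeans(pos[b, ]))^2))
    inter / mean(c(dist(pos[a, ]), dist(pos[b, ])))
  }
  r0 <- rat(layout_annealed(gb, anneal_schedule(edge_cut = 0, seed = 3)))
  r8 <- rat(layout_annealed(gb, anneal_schedule(edge_cut = 0.8, seed = 3)))
  expect_gt(r8, r0)
})

test_that("semantic layer assignment honours users, degree bands and ties", {
  g <- nv_graph(data.frame(source = c("gene", "gene"),
                           target = c("disease", "drug")))
  ul <- c(gene = 0, disease = 1, drug = 2)
  out <- assign_semantic_layers(g, semantic_params(n_layers = 3,
                                                   user_layers = ul))
  expect_equal(out[names(ul)], ul)
  expect_error(
    assign_semantic_layers(g, semantic_params(n_layers = 2,
                                              user_layers = ul)),
    "out of range")

  st <- make_star(10)   # hub degree 9, leaves degree 1
  la <- assign_semantic_layers(st, semantic_params(n_layers = 2))
  expect_equal(unname(la["n001"]), 0)
  expect_true(all(la[paste0("n", sprintf("%03d", 2:10))] == 1))

  ring <- make_cycle(14)  # all degrees equal: equal bins by id order
  lr <- assign_semantic_layers(ring, semantic_params(n_layers = 7))
  expect_equal(as.integer(table(lr)), rep(2L, 7))
  expect_equal(unname(lr[c("n001", "n002")]), c(0, 0))
})

test_that("semantic layout puts layers on exact equidistant z planes", {
  mk <- make_layered(c(4, 3, 3), 0.8, 0.2, seed = 2)
  sp <- semantic_params(n_layers = 3, spacing = 10,
                        user_layers = mk$layers)
  l <- layout_semantic(mk$graph, sp, fr_params(seed = 1, iterations = 100))
  expect_true(all(unclass(l)[, 3] %in% c(0, 10, 20)))

  sf <- make_scale_free(25, 2, seed = 4)
  l7 <- layout_semantic(sf, semantic_params(),
                        fr_params(seed = 1, iterations = 100))
  expect_equal(length(unique(unclass(l7)[, 3])), 7)

  one <- layout_semantic(make_clique(4),
                         semantic_params(n_layers = 1),
                         fr_params(seed = 1, iterations = 50))
  expect_true(all(unclass(one)[, 3] == 0))
})

test_that("hemisphere positions obey the spherical parameterization", {
  expect_equal(hemisphere_position(0, 10, hemisphere_spec(R = 1)),
               c(0, 0, 1))
  # every generated position satisfies x = R cos(lat) cos(lon),
  # y = R sin(lon) cos(lat), z = R sin(lat) for its latitude/longitude,
  # with 0 <= lat <= 90 degrees (upper hemisphere)
  spec <- hemisphere_spec(R = 2)
  for (r in 0:9) {
    p <- hemisphere_position(r, 10, spec)
    lat <- asin(p[3] / 2)
    expect_gte(lat, 0); expect_lte(lat, pi / 2)
    lon <- atan2(p[2], p[1])
    expect_equal(p, 2 * c(cos(lat) * cos(lon), sin(lon) * cos(lat),
                          sin(lat)), tolerance = 1e-12)
  }
  expect_error(hemisphere_position(5, 5), "range")
})

test_that("hemispherical layout: surface invariant, pole rule, spiral spacing", {
  st <- make_star(7)
  spec <- hemisphere_spec(R = 4, center = c(1, 2, 3))
  l <- layout_hemispherical(st, spec)
  pos <- unclass(l)
  expect_equal(unname(pos["n001", ]), c(1, 2, 3 + 4))  # hub at the pole
  radii <- sqrt(rowSums(sweep(pos, 2, spec$center)^2))
  expect_lt(max(abs(radii - 4)), 1e-9)
  deg <- node_degrees(st)
  expect_equal(unname(deg["n001"]), max(deg))

  # equal-area spiral: minimum great-circle gap of 100 isolated nodes is
  # within 30% of the ideal sqrt(2 pi R^2 / n) spacing
  iso <- nv_graph(nodes = data.frame(id = sprintf("i%03d", 1:100)))
  li <- layout_hemispherical(iso, hemisphere_spec(R = 1))
  p <- unclass(li)
  cosang <- tcrossprod(p)  # R = 1: dot products are cos(angle)
  min_gap <- acos(pmin(pmax(cosang, -1), 1))
  diag(min_gap) <- Inf
  ideal <- sqrt(2 * pi / 100)
  expect_gt(min(min_gap), 0.7 * ideal)
})

test_that("every engine is deterministic under a fixed seed with finite output", {
  g <- make_scale_free(15, 2, seed = 8)
  engines <- list(
    fr = function() layout_force_directed(g, fr_params(seed = 11,
                                                       iterations = 80)),
    linlog = function() layout_linlog(g, linlog_params(iterations = 80,
                                                       seed = 11)),
    hybrid = function() layout_hybrid(g, fr_params(seed = 11,
                                                   iterations = 80)),
    coarse = function() layout_coarsened(g, coarsen_params(seed = 11),
                                         fr_params(seed = 11,
                                                   iterations = 80)),
    anneal = function() layout_annealed(g, anneal_schedule(iterations = 80,
                                                           seed = 11)),
    semantic = function() layout_semantic(g, semantic_params(),
                                          fr_params(seed = 11,
                                                    iterations = 80)),
    hemi = function() layout_hemispherical(g))
  for (nm in names(engines)) {
    a <- engines[[nm]](); b <- engines[[nm]]()
    expect_identical(unclass(a), unclass(b), label = nm)
    expect_true(all(is.finite(unclass(a))), label = nm)
    expect_equal(nrow(unclass(a)), n_nodes(g), label = nm)
  }
})
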
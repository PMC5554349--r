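test_that("edge betweenness matches hand counts and the path-enumeration oracle", {
  bb <- make_barbell(3)
  eb <- edge_betweenness(bb)
  bridge <- eb$eb[eb$source == "a003" & eb$target == "b001"]
  expect_equal(bridge, 9)   # all 3 x 3 cross pairs

  se <- nv_graph(data.frame(source = "a", target = "b"))
  expect_equal(edge_betweenness(se)$eb, 1)

  cy <- make_cycle(4)
  expect_true(all(abs(edge_betweenness(cy)$eb -
                      edge_betweenness(cy)$eb[1]) < 1e-9))

  for (seed in 1:20) {
    g <- random_small_graph(seed, weighted = seed %% 2 == 0)
    eb <- edge_betweenness(g)
    or <- oracle_shortest_paths(g)$edge_betweenness
    key <- paste(pmin(eb$source, eb$target), pmax(eb$source, eb$target))
    expect_equal(eb$eb, unname(or[key]), tolerance = 1e-9)
  }
})

test_that("modularity follows the e_c/m - (d_c/2m)^2 form", {
  tt <- nv_graph(rbind(make_clique(3, "a")$edges, make_clique(3, "b")$edges))
  all_in_one <- nv_partition(stats::setNames(rep(0, 6), node_ids(tt)))
  expect_equal(modularity_score(tt, all_in_one), 0)

  right <- nv_partition(stats::setNames(
    as.integer(grepl("^b", node_ids(tt))), node_ids(tt)))
  expect_equal(modularity_score(tt, right), 0.5)
  expect_equal(modularity_score(tt, right),
               igraph::modularity(netvis3d:::as_igraph(tt),
                                  right$membership[node_ids(tt)] + 1))

  # brute force: 0.5 is the maximum over all 2-label partitions, and any
  # shuffle scores strictly less
  ids <- node_ids(tt)
  best <- -Inf
  for (mask in 1:(2^6 - 2)) {
    side <- as.logical(bitwAnd(bitwShiftR(mask, 0:5), 1L))
    q <- modularity_score(tt, stats::setNames(as.integer(side), ids))
    best <- max(best, q)
  }
  expect_equal(best, 0.5)
  shuffled <- nv_partition(stats::setNames(c(0, 1, 0, 1, 0, 1), ids))
  expect_lt(modularity_score(tt, shuffled), 0.5)

  expect_error(modularity_score(nv_graph(nodes = data.frame(id = "x")),
                                stats::setNames(0, "x")), "undefined")
})

test_that("Girvan-Newman removes the bridge first and respects protections", {
  bb <- make_barbell(3)
  tr <- cluster_girvan_newman(bb)
  expect_equal(tr$removed_edges$source[1], "a003")
  expect_equal(tr$removed_edges$target[1], "b001")
  expect_equal(tr$best_partition$k, 2)
  mem <- tr$best_partition$membership
  expect_length(unique(mem[c("a001", "a002", "a003")]), 1)
  expect_length(unique(mem[c("b001", "b002", "b003")]), 1)
  expect_equal(tr$best_modularity, modularity_score(bb, tr$best_partition))
  # never below the untouched component partition
  expect_gte(tr$best_modularity,
             modularity_score(bb, netvis3d:::.component_partition(bb)))

  # pendant edge is never removed (would isolate the pendant)
  tri <- make_cycle(3)
  pend <- nv_graph(rbind(tri$edges,
                         data.frame(source = "n001", target = "p", weight = 1,
                                    directed = FALSE, color = NA,
                                    pattern = NA)))
  tr2 <- cluster_girvan_newman(pend, removal_fraction = 1)
  expect_false(any(tr2$removed_edges$target == "p" |
                   tr2$removed_edges$source == "p"))

  # star: every edge ends at a leaf, nothing is removable
  st <- make_star(6)
  tr3 <- cluster_girvan_newman(st, removal_fraction = 1)
  expect_equal(nrow(tr3$removed_edges), 0)
  expect_equal(tr3$best_partition$k, 1)

  expect_error(cluster_girvan_newman(bb, removal_fraction = 1.5),
               "removal_fraction")
})

test_that("MCL finds flow clusters and stays column-stochastic", {
  bb <- make_barbell(3)
  p <- cluster_mcl(bb)
  expect_equal(p$k, 2)
  expect_length(unique(p$membership[c("a001", "a002", "a003")]), 1)
  expect_lt(attr(p, "col_dev"), 1e-9)

  # flow cannot cross components
  two <- nv_graph(rbind(make_clique(3, "a")$edges, make_clique(4, "b")$edges))
  pt <- cluster_mcl(two)
  comp <- connected_components(two)
  for (cc in comp)
    expect_length(unique(pt$membership[cc]), 1)

  single <- nv_graph(nodes = data.frame(id = "s"))
  ps <- cluster_mcl(single)
  expect_equal(ps$k, 1)

  expect_equal(sort(names(p$membership)), sort(node_ids(bb)))
})

test_that("raising MCL inflation never decreases cluster count", {
  for (seed in 1:5) {
    g <- make_modular(3, 8, 0.6, 0.05, seed = seed)$graph
    ks <- vapply(c(1.4, 2, 3, 5), function(infl)
      cluster_mcl(g, mcl_params(inflation = infl))$k, integer(1))
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("leading-eigenvector clustering splits by modularity", {
  bb <- make_barbell(3)
  p <- cluster_leading_eigenvector(bb)
  expect_equal(p$k, 2)
  expect_length(unique(p$membership[c("a001", "a002", "a003")]), 1)

  k5 <- make_clique(5)
  expect_equal(cluster_leading_eigenvector(k5)$k, 1)
  # brute force: no bipartition of K5 has positive modularity gain
  ids <- node_ids(k5)
  gains <- vapply(1:(2^5 - 2), function(mask) {
    side <- as.logical(bitwAnd(bitwShiftR(mask, 0:4), 1L))
    modularity_score(k5, stats::setNames(as.integer(side), ids))
  }, numeric(1))
  expect_true(all(gains <= 0 + 1e-12))

  # a heavy bridge can merge the barbell; whatever is returned must beat or
  # match both candidate partitions
  heavy <- make_barbell(3, bridge_weight = 100)
  ph <- cluster_leading_eigenvector(heavy)
  q_out <- modularity_score(heavy, ph)
  q_one <- modularity_score(
    heavy, stats::setNames(rep(0, 6), node_ids(heavy)))
  q_tri <- modularity_score(
    heavy, stats::setNames(rep(c(0, 1), each = 3), node_ids(heavy)))
  expect_gte(q_out, max(q_one, q_tri) - 1e-12)
})

test_that("all clustering algorithms return exact covers of V", {
  g <- make_modular(3, 6, 0.8, 0.05, seed = 2)$graph
  for (p in list(cluster_girvan_newman(g)$best_partition,
                 cluster_mcl(g),
                 cluster_leading_eigenvector(g))) {
    expect_setequal(names(p$membership), node_ids(g))
    expect_equal(sort(unique(unname(p$membership))), 0:(p$k - 1))
  }
})

test_that("strongly modular fixtures are recovered", {
  mk <- make_modular(3, 8, 0.9, 0.02, seed = 1)
  expect_true(partitions_equal(cluster_girvan_newman(mk$graph)$best_partition,
                               mk$partition))
  expect_true(partitions_equal(cluster_mcl(mk$graph), mk$partition))
  # leading-eigenvector is a greedy modularity maximizer and may split off
  # single boundary nodes; it must still land near the planted optimum
  le <- cluster_leading_eigenvector(mk$graph)
  q_truth <- modularity_score(mk$graph, mk$partition)
  expect_gt(modularity_score(mk$graph, le), q_truth - 0.07)
  tab <- table(le$membership[names(mk$partition$membership)],
               mk$partition$membership)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gt(purity, 0.9)
})
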
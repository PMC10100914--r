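test_that("centralities match closed forms on canonical graphs", {
  k5 <- compute_centralities(make_fixture_graph("complete", 5))
  expect_true(all(k5$degree == 4))
  expect_true(all(k5$betweenness == 0))
  expect_true(all(k5$mean_abs_weight == 1))

  p3 <- compute_centralities(make_fixture_graph("path", 3))
  expect_equal(p3$degree, c(1L, 2L, 1L))
  expect_equal(p3$betweenness, c(0, 1, 0))

  # sum of degrees = 2 x edge count
  er <- random_graph(15, 0.25, seed = 4)
  ct <- compute_centralities(er)
  expect_equal(sum(ct$degree), 2 * igraph::ecount(er$graph))
})

test_that("betweenness agrees with brute-force shortest-path enumeration", {
  # bridge endpoints of a barbell dominate betweenness
  bb <- make_fixture_graph("barbell", 10)
  ct <- compute_centralities(bb)
  oracle <- brute_betweenness(bb)
  expect_equal(ct$betweenness, oracle, tolerance = 1e-10)
  bridge <- order(oracle, decreasing = TRUE)[1:2]
  expect_equal(sort(ct$betweenness, decreasing = TRUE)[1:2],
               sort(oracle[bridge], decreasing = TRUE))
  expect_gt(min(oracle[bridge]), max(oracle[-bridge]))

  for (sd in 1:5) {
    g <- random_graph(8 + sd, 0.3, seed = sd * 13)
    expect_equal(compute_centralities(g)$betweenness, brute_betweenness(g),
                 tolerance = 1e-10, info = paste("seed", sd))
  }
})

test_that("mean absolute incident weight summarizes signed edges", {
  g <- igraph::graph_from_literal(a - b, a - c, b - c)
  igraph::E(g)$weight <- c(0.5, -1.5, 2)
  net <- interaction_network(g)
  ct <- compute_centralities(net)
  expect_equal(ct$mean_abs_weight[ct$node == "a"], (0.5 + 1.5) / 2)
  expect_equal(ct$mean_abs_weight[ct$node == "b"], (0.5 + 2) / 2)
  expect_equal(ct$mean_abs_weight[ct$node == "c"], (1.5 + 2) / 2)
})

test_that("keystones are the joint top tail of degree and betweenness", {
  bb <- make_fixture_graph("barbell", 10)
  ct <- compute_centralities(bb)
  ks <- keystone_nodes(ct, percentile = 0.8)
  # brute-force ranking: bridge endpoints are in the top 20% of both metrics
  oracle <- brute_betweenness(bb)
  bridge <- ct$node[order(oracle, decreasing = TRUE)[1:2]]
  expect_true(all(bridge %in% ks$keystone_ids))
  expect_true(all(ks$flags$is_keystone == (ct$degree >= ks$degree_threshold &
                                             ct$betweenness >= ks$betweenness_threshold)))

  # all-tied metrics: every node is a keystone (documented degenerate case)
  k6 <- keystone_nodes(compute_centralities(make_fixture_graph("complete", 6)))
  expect_length(k6$keystone_ids, 6)
})

test_that("core extraction follows the fixed filter order", {
  # star: every node passes the median cutoffs, leaves fail min_edges,
  # the hub is then isolated -> empty core
  s10 <- make_fixture_graph("star", 10)
  expect_warning(core <- core_network(s10, percentile = 0.5, min_edges = 3),
                 "empty")
  expect_equal(igraph::vcount(core$graph), 0)
  expect_true(core$provenance$empty)

  # complete graph: all tied, everything survives
  k6 <- make_fixture_graph("complete", 6)
  core6 <- core_network(k6, percentile = 0.5, min_edges = 3)
  expect_equal(igraph::vcount(core6$graph), 6)
  expect_equal(igraph::ecount(core6$graph), 15)

  # percentile 0 reduces to min_edges filtering (plus isolated-node drop)
  er <- random_graph(20, 0.15, seed = 9)
  c0 <- suppressWarnings(core_network(er, percentile = 0, min_edges = 3))
  deg <- igraph::degree(er$graph)
  manual <- igraph::induced_subgraph(er$graph, igraph::V(er$graph)[deg >= 3])
  manual <- igraph::delete_vertices(manual, igraph::V(manual)[igraph::degree(manual) == 0])
  expect_setequal(igraph::V(c0$graph)$name, igraph::V(manual)$name)

  # core is always a subgraph; node set shrinks as min_edges grows
  prev <- Inf
  for (me in 1:4) {
    ci <- suppressWarnings(core_network(er, percentile = 0.5, min_edges = me))
    expect_true(all(igraph::V(ci$graph)$name %in% igraph::V(er$graph)$name))
    expect_true(all(edge_set(ci) %in% edge_set(er)))
    expect_lte(igraph::vcount(ci$graph), prev)
    prev <- igraph::vcount(ci$graph)
  }
})

test_that("domain metric comparison behaves under null, shift, and planted weight inflation", {
  # identical groups: p ~ 1, equal medians
  tbl <- data.frame(node = paste0("n", 1:20), degree = rep(5L, 20),
                    betweenness = rep(2, 20), mean_abs_weight = rep(0.5, 20),
                    domain = rep(c("bacteria", "fungus"), each = 10))
  class(tbl) <- c("centrality_table", "data.frame")
  same <- compare_domain_metric(tbl, "degree", "bacteria", "fungus")
  expect_gt(same$p_value, 0.9)
  expect_equal(same$median_a, same$median_b)

  # a large shift is detected at n = 30 per group
  set.seed(8)
  tbl2 <- data.frame(
    node = paste0("n", 1:60),
    degree = c(rpois(30, 5), rpois(30, 5) + 40L),
    betweenness = rep(1, 60), mean_abs_weight = rep(1, 60),
    domain = rep(c("bacteria", "fungus"), each = 30)
  )
  shift <- compare_domain_metric(tbl2, "degree", "bacteria", "fungus")
  expect_lt(shift$p_value, 0.001)
  expect_lt(shift$median_a, shift$median_b)
  # fungi own the pooled top-20% tail here
  expect_gt(shift$top_share_b, 0.9)

  # inflated fungal couplings push fungal mean_abs_weight up
  set.seed(10)
  tbl3 <- data.frame(
    node = paste0("n", 1:60),
    degree = rpois(60, 4), betweenness = rexp(60),
    mean_abs_weight = c(abs(rnorm(40, 0.2, 0.05)), abs(rnorm(20, 0.6, 0.1))),
    domain = c(rep("bacteria", 40), rep("fungus", 20))
  )
  wcmp <- compare_domain_metric(tbl3, "mean_abs_weight", "fungus", "bacteria")
  expect_lt(wcmp$p_value, 1e-4)
  expect_gt(wcmp$median_a, wcmp$median_b)

  expect_error(compare_domain_metric(tbl, "degree", "bacteria", "archaea"),
               "archaea")
})
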
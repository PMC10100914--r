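test_that("the penalty path is log-spaced, strictly decreasing, of length nlambda", {
  tm <- make_true_model(12, 0.1, seed = 1)
  ct <- simulate_counts(tm, 150, seed = 2)
  sp <- stars_path(clr_transform(ct), netinfer_params(seed = 1))
  expect_length(sp$lambdas, 20)
  expect_true(all(diff(sp$lambdas) < 0))
  expect_equal(sp$lambdas[20] / sp$lambdas[1], 0.005, tolerance = 1e-10)
  # selection frequencies live in [0, 1] and the instability statistic is
  # the mean over pairs of 2 f (1 - f)
  expect_true(all(sp$freq >= 0 & sp$freq <= 1))
  p <- length(sp$taxa)
  ut <- upper.tri(matrix(0, p, p))
  recompute <- vapply(seq_along(sp$lambdas), function(l) {
    f <- sp$freq[, , l][ut]
    mean(2 * f * (1 - f))
  }, numeric(1))
  expect_equal(sp$instability, recompute)
  expect_equal(sp$monotonized_instability, cummax(sp$instability))
})

test_that("a duplicated taxon column is selected at stability frequency 1", {
  set.seed(42)
  n <- 200
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 2] <- X[, 1]  # perfect dependence
  colnames(X) <- paste0("t", 1:8)
  sp <- stars_path(X, netinfer_params(seed = 3))
  expect_equal(max(sp$freq[1, 2, ]), 1)
  expect_equal(sp$freq[1, 2, sp$selected_index], 1)
})

test_that("null (identity-precision) data yields a near-empty selected graph", {
  # single-marker community: the null hypothesis of no conditional
  # dependence holds in CLR space up to a 1/(p-1) closure term; a tiny
  # second marker block would instead carry a genuine closure clique
  for (sd in 1:2) {
    tm <- make_true_model(20, 1e-9, seed = sd,
                          domain_fractions = c(bacteria = 1, archaea = 0, fungus = 0))
    ct <- simulate_counts(tm, 300, zero_inflation = 0, seed = sd + 50)
    net <- suppressWarnings(infer_network(clr_transform(ct), netinfer_params(seed = sd)))
    expect_lte(igraph::ecount(net$graph), 2)
  }
})

test_that("small CLR marker blocks carry a closure clique that inference reports", {
  # documented limitation: with only 4 fungal taxa, per-block CLR forces
  # pairwise correlations of about -1/3 among them, and those edges are
  # stably selected even under an identity-precision truth
  tm <- make_true_model(20, 1e-9, seed = 1,
                        domain_fractions = c(bacteria = 0.55, archaea = 0.25, fungus = 0.20))
  ct <- simulate_counts(tm, 300, zero_inflation = 0, seed = 51)
  net <- suppressWarnings(infer_network(clr_transform(ct), netinfer_params(seed = 1),
                                        domain = tm$domain_of))
  e <- igraph::ends(net$graph, igraph::E(net$graph))
  expect_gt(nrow(e), 0)
  fungal <- names(tm$domain_of)[tm$domain_of == "fungus"]
  expect_true(all(e[, 1] %in% fungal & e[, 2] %in% fungal))
  expect_true(all(igraph::E(net$graph)$weight < 0))
})

test_that("latent rank selection is a pass-through at rank 0 and detects a planted factor", {
  tm <- make_true_model(25, 0.06, seed = 7, domain_fractions = c(bacteria = 1, archaea = 0, fungus = 0))
  ct <- simulate_counts(tm, 300, zero_inflation = 0, seed = 8)
  X <- unclass(as.matrix(clr_transform(ct)))

  lr0 <- latent_rank_select(X, netinfer_params(latent_rank_max = 0, seed = 1))
  expect_equal(lr0$rank, 0L)
  expect_identical(lr0$adjusted, X)

  # add one strong dense factor on top of the sparse structure
  set.seed(9)
  f <- rnorm(nrow(X))
  load <- rnorm(ncol(X), mean = 2, sd = 0.2)
  Xf <- X + outer(f, load)
  colnames(Xf) <- colnames(X)
  params <- netinfer_params(latent_rank_max = 2, seed = 2)
  lr <- latent_rank_select(Xf, params)
  expect_gte(lr$rank, 1L)
  expect_true(all(is.finite(lr$ebic)))

  # removing the factor improves edge recovery over ignoring it
  net_adj <- suppressWarnings(infer_network(Xf, params))
  net_raw <- suppressWarnings(infer_network(Xf, netinfer_params(latent_rank_max = 0, seed = 2)))
  f1 <- function(m) 2 * m["precision"] * m["recall"] /
    max(m["precision"] + m["recall"], 1e-12)
  expect_gt(f1(recovery_metrics(net_adj, tm)), f1(recovery_metrics(net_raw, tm)))
  expect_equal(net_adj$provenance$latent_rank, lr$rank)
})

test_that("inference is deterministic and annotates nodes and provenance", {
  tm <- make_true_model(15, 0.08, seed = 11)
  ct <- simulate_counts(tm, 200, seed = 12)
  clr <- clr_transform(ct)
  n1 <- suppressWarnings(infer_network(clr, netinfer_params(seed = 5),
                                       domain = tm$domain_of, marker = tm$marker_of))
  n2 <- suppressWarnings(infer_network(clr, netinfer_params(seed = 5),
                                       domain = tm$domain_of, marker = tm$marker_of))
  expect_identical(edge_set(n1), edge_set(n2))
  expect_identical(igraph::E(n1$graph)$weight, igraph::E(n2$graph)$weight)
  expect_equal(n1$n_input_taxa, 15)
  expect_true(all(igraph::V(n1$graph)$domain %in% c("bacteria", "archaea", "fungus")))
  # no self edges, finite nonzero weights, no isolated nodes
  expect_false(any(igraph::which_loop(n1$graph)))
  expect_true(all(is.finite(igraph::E(n1$graph)$weight) & igraph::E(n1$graph)$weight != 0))
  expect_true(all(igraph::degree(n1$graph) > 0))
  expect_true(all(igraph::E(n1$graph)$stability >= 0 & igraph::E(n1$graph)$stability <= 1))
})

test_that("edge signs follow the empirical CLR correlation for strongly coupled pairs", {
  set.seed(31)
  n <- 300
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 2] <- X[, 1] + rnorm(n, sd = 0.3)   # strong positive coupling
  X[, 4] <- -X[, 3] + rnorm(n, sd = 0.3)  # strong negative coupling
  colnames(X) <- paste0("t", 1:10)
  net <- suppressWarnings(infer_network(X, netinfer_params(seed = 4)))
  g <- net$graph
  e12 <- igraph::get_edge_ids(g, c("t1", "t2"))
  e34 <- igraph::get_edge_ids(g, c("t3", "t4"))
  expect_true(e12 > 0 && e34 > 0)
  expect_gt(igraph::E(g)$weight[e12], 0)
  expect_lt(igraph::E(g)$weight[e34], 0)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(100 * 5), 100, 5)
  X[, 3] <- 2
  colnames(X) <- paste0("t", 1:5)
  expect_error(stars_path(X, netinfer_params(seed = 1)), "constant")
  expect_error(stars_path(matrix(rnorm(20), 10, 2), netinfer_params(seed = 1)),
               "at least 3 taxa")
  small <- matrix(rnorm(20 * 4), 20, 4)
  oversized <- netinfer_params(seed = 1, subsample_size = function(n) n + 5)
  expect_error(stars_path(small, oversized), "subsample size")
  expect_error(netinfer_params(stars_threshold = 0), "stars_threshold")
  expect_error(netinfer_params(n_reps = 1), "n_reps")
})
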
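test_that("fixture graphs match closed-form edge counts and degree sequences", {
  k10 <- make_fixture_graph("complete", 10)
  expect_equal(igraph::ecount(k10$graph), 45)
  expect_true(all(igraph::degree(k10$graph) == 9))

  expect_equal(igraph::ecount(make_fixture_graph("edgeless", 10)$graph), 0)

  s10 <- make_fixture_graph("star", 10)
  deg <- sort(igraph::degree(s10$graph))
  expect_equal(unname(deg), c(rep(1, 9), 9))

  p5 <- make_fixture_graph("path", 5)
  expect_equal(igraph::ecount(p5$graph), 4)
  expect_equal(sort(unname(igraph::degree(p5$graph))), c(1, 1, 2, 2, 2))

  bb <- make_fixture_graph("barbell", 10)
  expect_equal(igraph::ecount(bb$graph), 2 * choose(5, 2) + 1)
  expect_equal(sort(unname(igraph::degree(bb$graph)), decreasing = TRUE)[1:2], c(5, 5))

  er1 <- make_fixture_graph("erdos_renyi", 20, p_edge = 0.3, seed = 7)
  er2 <- make_fixture_graph("erdos_renyi", 20, p_edge = 0.3, seed = 7)
  expect_identical(edge_set(er1), edge_set(er2))

  expect_error(make_fixture_graph("hypercube", 8), "unknown graph kind")
  expect_error(make_fixture_graph("complete", 1), "n must be")
  expect_error(make_fixture_graph("erdos_renyi", 10), "p_edge")
})

test_that("true models are positive definite with edge set equal to the precision support", {
  tm <- make_true_model(40, 0.05, seed = 3)
  expect_silent(chol(tm$precision))
  expect_equal(tm$precision, t(tm$precision))

  support <- which(tm$precision != 0 & upper.tri(tm$precision), arr.ind = TRUE)
  sa <- rownames(tm$precision)[support[, 1]]
  sb <- rownames(tm$precision)[support[, 2]]
  support_keys <- paste(pmin(sa, sb), pmax(sa, sb), sep = "|")
  expect_setequal(true_edge_set(tm), support_keys)

  # edge count near density * n_pairs (well within binomial range)
  n_pairs <- choose(40, 2)
  expect_gt(nrow(tm$true_edges), qbinom(1e-4, n_pairs, 0.05))
  expect_lt(nrow(tm$true_edges), qbinom(1 - 1e-4, n_pairs, 0.05))

  # every taxon gets exactly one domain and one marker
  expect_equal(sort(names(tm$domain_of)), sort(rownames(tm$precision)))
  expect_true(all(tm$domain_of %in% c("bacteria", "archaea", "fungus")))
  expect_true(all(tm$marker_of[tm$domain_of == "fungus"] == "18S"))

  # vanishing density gives a diagonal matrix
  tm0 <- make_true_model(4, 1e-9, seed = 1)
  expect_equal(nrow(tm0$true_edges), 0)
  expect_equal(tm0$precision, diag(4), ignore_attr = TRUE)

  expect_identical(make_true_model(12, 0.1, seed = 5)$precision,
                   make_true_model(12, 0.1, seed = 5)$precision)
})

test_that("simulated counts are deterministic, sum to the drawn depth, and honor zero inflation", {
  tm <- make_true_model(30, 1e-9, seed = 2)  # independent taxa

  a <- simulate_counts(tm, 50, seed = 11)
  b <- simulate_counts(tm, 50, seed = 11)
  expect_identical(a$counts, b$counts)

  clean <- simulate_counts(tm, 50, zero_inflation = 0, seed = 12)
  expect_equal(unname(rowSums(clean$counts)), as.numeric(attr(clean, "library_depth")))

  # extra-zero fraction among baseline-nonzero entries matches the rate
  z0 <- simulate_counts(tm, 500, zero_inflation = 0, seed = 13)
  z3 <- simulate_counts(tm, 500, zero_inflation = 0.3, seed = 13)
  nonzero_base <- z0$counts > 0
  extra <- mean(z3$counts[nonzero_base] == 0)
  expect_lt(abs(extra - 0.3), 0.05)

  expect_error(simulate_counts(tm, 50, zero_inflation = 1), "zero_inflation")
  expect_error(simulate_counts(tm, 1), "n_samples")
})

test_that("independent taxa show near-zero CLR correlations at large n", {
  tm <- make_true_model(30, 1e-9, seed = 4)
  ct <- simulate_counts(tm, 2000, zero_inflation = 0, seed = 21)
  clr <- clr_transform(ct)
  cc <- cor(unclass(as.matrix(clr)))
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.05)
})

test_that("metadata profiles peak in the SMTZ and are reproducible", {
  slices <- lapply(0:5, function(i) c(i * 3, (i + 1) * 3))
  meta <- simulate_metadata(c("siteA", "siteB"), slices, seed = 5)
  expect_equal(nrow(meta), 12)
  expect_true(all(meta$depth_top_cm < meta$depth_bottom_cm))

  # noise-free curve attains its maximum inside the SMTZ
  quiet <- simulate_metadata("s1", slices, smtz_interval_cm = c(10, 13),
                             methane_peak = 5, noise_cv = 0, seed = 1)
  peak_slice <- quiet[which.max(quiet$methane), ]
  mid <- (peak_slice$depth_top_cm + peak_slice$depth_bottom_cm) / 2
  expect_gte(mid, 10 - 1.5)  # slice midpoints are 3 cm apart
  expect_lte(mid, 13 + 1.5)

  # sulfate decays with depth in the noise-free profile
  expect_true(all(diff(quiet$sulfate) < 0))

  m1 <- simulate_metadata("s", slices, seed = 9)
  m2 <- simulate_metadata("s", slices, seed = 9)
  expect_identical(m1$methane, m2$methane)

  expect_error(simulate_metadata(character(0), slices), "site")
  expect_error(simulate_metadata("s", slices, smtz_interval_cm = c(40, 45)),
               "within the covered depth range")
})

test_that("planted balance signals separate classes and degenerate cases error", {
  # unit-scale latent noise: the planted-signal experiments quantify the
  # balance shift against per-taxon log-fluctuations of sd 1
  tm <- make_true_model(30, 1e-9, seed = 6)
  ct <- simulate_counts(tm, 200, zero_inflation = 0.05, latent_scale = 1, seed = 31)

  expect_error(plant_balance_signal(ct, "t1", "t1", 2), "overlap")
  expect_error(plant_balance_signal(ct, "t1", "nope", 2), "not in table")

  # zero effect leaves the table untouched
  p0 <- plant_balance_signal(ct, "t1", "t2", 0, seed = 1)
  expect_identical(p0$counts$counts, ct$counts)

  # plant into the two most prevalent taxa (planting into near-absent taxa
  # would measure dropout, not the balance); effect 2 separates classes
  planted <- names(sort(colMeans(ct$counts > 0), decreasing = TRUE))[1:2]
  pl <- plant_balance_signal(ct, planted[1], planted[2], 2, seed = 2)
  b <- balance_value(pl$counts, planted[1], planted[2])
  y <- pl$signal$response == "high"
  auc <- (sum(rank(b)[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
  expect_gt(auc, 0.9)

  # labels are balanced
  expect_equal(abs(diff(as.numeric(table(pl$signal$response)))) <= 1, TRUE)
})
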
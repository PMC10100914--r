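#' Node centralities and edge-weight summaries
#'
#' Computes, for every node: degree (unweighted edge count), betweenness
#' centrality (number of shortest paths passing through the node, unweighted
#' topology, standard multiplicity normalization, not rescaled by network
#' size) and the mean absolute weight of incident edges. Signed weights enter
#' only through their magnitudes; shortest paths ignore weights entirely
#' because co-occurrence strength has no canonical mapping to distance.
#'
#' @param net An [interaction_network] or igraph.
#' @return A `centrality_table` data frame: `node`, `degree`, `betweenness`,
#'   `mean_abs_weight`, `domain`.
#' @export
compute_centralities <- function(net) {
  g <- as_graph(net)
  N <- igraph::vcount(g)
  if (N == 0) stop("network is empty")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
  w <- abs(igraph::E(g)$weight %||% rep(1, igraph::ecount(g)))
  maw <- if (igraph::ecount(g) > 0) {
    igraph::strength(g, weights = w) / pmax(deg, 1)
  } else {
    rep(0, N)
  }
  maw[deg == 0] <- 0
  out <- data.frame(
    node = igraph::V(g)$name %||% as.character(seq_len(N)),
    degree = as.integer(deg),
    betweenness = as.numeric(btw),
    mean_abs_weight = as.numeric(maw),
    domain = igraph::V(g)$domain %||% rep(NA_character_, N),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Keystone taxa by joint centrality percentile
#'
#' A keystone taxon sits in the top `(1 - percentile)` tail of both degree
#' and betweenness. Thresholds are the linear-interpolation empirical
#' quantiles of each metric at `percentile`; nodes at or above both
#' thresholds are keystones, so ties at a threshold are included (with
#' all-tied metrics every node qualifies; this degenerate case is
#' intentional).
#'
#' @param table A `centrality_table` from [compute_centralities()].
#' @param percentile Quantile level of the cutoffs (default 0.80: top 20th
#'   percentiles).
#' @return A `keystone_report`: `degree_threshold`, `betweenness_threshold`,
#'   `keystone_ids`, per-node `flags` data frame, `percentile`.
#' @export
keystone_nodes <- function(table, percentile = 0.80) {
  stopifnot(inherits(table, "data.frame"), nrow(table) > 0)
  dthr <- unname(stats::quantile(table$degree, percentile, type = 7))
  bthr <- unname(stats::quantile(table$betweenness, percentile, type = 7))
  is_key <- table$degree >= dthr & table$betweenness >= bthr
  flags <- data.frame(node = table$node, domain = table$domain,
                      is_keystone = is_key, stringsAsFactors = FALSE)
  structure(
    list(degree_threshold = dthr, betweenness_threshold = bthr,
         keystone_ids = table$node[is_key], flags = flags,
         percentile = percentile),
    class = "keystone_report"
  )
}

#' @export
print.keystone_report <- function(x, ...) {
  cat(sprintf("keystone_report: %d keystones (degree >= %.3g and betweenness >= %.3g, percentile %.2f)\n",
              length(x$keystone_ids), x$degree_threshold, x$betweenness_threshold,
              x$percentile))
  invisible(x)
}

#' Extract the core network
#'
#' Reduces a network to its structural core in a fixed order: (1) keep nodes
#' in the top `(1 - percentile)` of both degree and betweenness (ties at the
#' threshold included), (2) take the induced subgraph, (3) drop nodes with
#' fewer than `min_edges` edges in that subgraph, (4) drop any node left
#' isolated. An empty core is returned as an empty network flagged in its
#' provenance, with a warning.
#'
#' @param net An [interaction_network] or igraph.
#' @param percentile Joint centrality cutoff level (default 0.50).
#' @param min_edges Minimum edge count within the core (default 3).
#' @return An [interaction_network] that is an induced subgraph of `net`.
#' @export
core_network <- function(net, percentile = 0.50, min_edges = 3) {
  g <- as_graph(net)
  if (igraph::vcount(g) == 0) stop("network is empty")
  ct <- compute_centralities(g)
  dthr <- unname(stats::quantile(ct$degree, percentile, type = 7))
  bthr <- unname(stats::quantile(ct$betweenness, percentile, type = 7))
  keep <- ct$node[ct$degree >= dthr & ct$betweenness >= bthr]
  sub <- igraph::induced_subgraph(g, igraph::V(g)[name %in% keep])
  sub <- igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) < min_edges])
  sub <- igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
  empty <- igraph::vcount(sub) == 0
  if (empty) warning("core network is empty after filtering")
  prov <- list(core_of = TRUE, percentile = percentile, min_edges = min_edges,
               degree_threshold = dthr, betweenness_threshold = bthr,
               empty = empty)
  interaction_network(sub, provenance = prov,
                      n_input_taxa = igraph::vcount(g))
}

#' Compare a centrality metric between two domains
#'
#' Two-sample rank test (Mann-Whitney / rank-sum) on the metric values of the
#' nodes of two domains, with each domain's share of the pooled top-20% tail
#' of the metric. The unpaired rank-sum form is used because the domain
#' groups are independent samples of different sizes; there is no pairing
#' that would license a signed-rank test.
#'
#' @param table A `centrality_table`.
#' @param metric One of `"degree"`, `"betweenness"`, `"mean_abs_weight"`.
#' @param domain_a,domain_b Domain labels present in the table with >= 2
#'   nodes each.
#' @param tail_percentile Quantile level defining the pooled top tail
#'   (default 0.80).
#' @return A `domain_comparison`: `statistic`, `p_value`, `median_a`,
#'   `median_b`, `top_share_a`, `top_share_b`, `metric`, `test`.
#' @export
compare_domain_metric <- function(table, metric = c("degree", "betweenness", "mean_abs_weight"),
                                  domain_a, domain_b, tail_percentile = 0.80) {
  metric <- match.arg(metric)
  for (d in c(domain_a, domain_b)) {
    if (sum(table$domain == d, na.rm = TRUE) < 2) {
      stop("domain '", d, "' missing or has fewer than 2 nodes")
    }
  }
  xa <- table[[metric]][table$domain == domain_a]
  xb <- table[[metric]][table$domain == domain_b]
  if (stats::var(c(xa, xb)) == 0) {
    # every value tied: no evidence of a difference by convention
    wt <- list(statistic = length(xa) * length(xb) / 2, p.value = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
  }

  pooled_thr <- unname(stats::quantile(table[[metric]], tail_percentile, type = 7))
  top <- table[table[[metric]] >= pooled_thr, , drop = FALSE]
  n_top <- max(nrow(top), 1L)
  structure(
    list(
      statistic = unname(wt$statistic), p_value = wt$p.value,
      median_a = stats::median(xa), median_b = stats::median(xb),
      top_share_a = sum(top$domain == domain_a, na.rm = TRUE) / n_top,
      top_share_b = sum(top$domain == domain_b, na.rm = TRUE) / n_top,
      metric = metric, domain_a = domain_a, domain_b = domain_b,
      test = "two-sample rank-sum (Mann-Whitney)"
    ),
    class = "domain_comparison"
  )
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat(sprintf("domain_comparison (%s): %s vs %s\n", x$metric, x$domain_a, x$domain_b))
  cat(sprintf("  medians %.4g vs %.4g; top-tail shares %.2f vs %.2f; p = %.3g (%s)\n",
              x$median_a, x$median_b, x$top_share_a, x$top_share_b, x$p_value, x$test))
  invisible(x)
}
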
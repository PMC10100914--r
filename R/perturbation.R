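#' Random-attack robustness and vulnerability of a network
#'
#' Simulates the stochastic removal of taxa from the community. In each
#' iteration the nodes are removed one at a time in a uniformly random order;
#' after each removal the relative size of the largest connected component,
#' `sigma(i) = |largest component| / N` (relative to the initial node count
#' `N`, with `sigma(N) = 0` once nothing is left), is recorded. Normalized
#' robustness is the area under that curve, `R = (1/N) * sum_{i=1..N}
#' sigma(i)`, and vulnerability is `V = 0.5 - R`. A complete graph attains
#' the minimum `V = 1/(2N)`; an edgeless graph the maximum
#' `V = 0.5 - (N-1)/N^2`.
#'
#' The per-iteration computation processes the removal order in reverse as
#' node additions tracked by a union-find structure, so each iteration costs
#' near-linear time in nodes plus edges.
#'
#' @param net An [interaction_network] or igraph.
#' @param n_iter Number of random removal orders (iterations).
#' @param seed Master RNG seed; each iteration's permutation is drawn under a
#'   deterministically derived per-iteration seed.
#' @param permutations Optional integer matrix (`n_iter` x `N`) of explicit
#'   removal orders, overriding the random draw. Used to couple attacks
#'   across networks sharing a node set (e.g. monotonicity analyses).
#' @return An `attack_result`: `n_nodes`, `n_iter`, per-iteration `R` and
#'   `V`, the averaged curve `mean_sigma_curve`, `V_mean`, `V_sd`, `seed`.
#' @export
attack_robustness <- function(net, n_iter = 10000, seed = NULL, permutations = NULL) {
  g <- as_graph(net)
  N <- igraph::vcount(g)
  if (N < 2) stop("network must have at least 2 nodes")
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)

  if (is.null(permutations)) {
    if (n_iter < 1) stop("n_iter must be >= 1")
    permutations <- matrix(0L, n_iter, N)
    with_seed(seed %||% 1L, {
      for (it in seq_len(n_iter)) {
        set.seed(derive_seed(seed %||% 1L, it))
        permutations[it, ] <- sample.int(N)
      }
    })
  } else {
    permutations <- matrix(as.integer(permutations), ncol = N)
    n_iter <- nrow(permutations)
  }

  sig <- .attack_sigma(adj, permutations, N)
  R <- rowSums(sig) / N
  V <- 0.5 - R
  structure(
    list(
      n_nodes = N, n_iter = n_iter, R = R, V = V,
      mean_sigma_curve = colMeans(sig),
      V_mean = mean(V), V_sd = stats::sd(V),
      seed = seed
    ),
    class = "attack_result"
  )
}

# sigma curves for a batch of removal permutations; sig[it, i] is the
# relative largest-component size after removing the first i nodes of
# permutation `it` (the column i = N is always 0).
.attack_sigma <- function(adj, perms, N) {
  n_iter <- nrow(perms)
  sig <- matrix(0, n_iter, N)
  for (it in seq_len(n_iter)) {
    perm <- perms[it, ]
    parent <- integer(N)  # 0 marks a node not yet re-added
    sz <- integer(N)
    maxc <- 0L
    for (k in seq_len(N - 1L)) {
      v <- perm[N - k + 1L]
      parent[v] <- v
      sz[v] <- 1L
      if (maxc < 1L) maxc <- 1L
      for (u in adj[[v]]) {
        if (parent[u] == 0L) next
        ru <- u
        while (parent[ru] != ru) { parent[ru] <- parent[parent[ru]]; ru <- parent[ru] }
        rv <- v
        while (parent[rv] != rv) { parent[rv] <- parent[parent[rv]]; rv <- parent[rv] }
        if (ru != rv) {
          if (sz[ru] < sz[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
          parent[rv] <- ru
          sz[ru] <- sz[ru] + sz[rv]
          if (sz[ru] > maxc) maxc <- sz[ru]
        }
      }
      sig[it, N - k] <- maxc
    }
  }
  sig / N
}

#' @export
print.attack_result <- function(x, ...) {
  cat("attack_result:", x$n_nodes, "nodes,", x$n_iter, "iterations\n")
  cat(sprintf("  V_mean = %.4f (sd %.4f); R_mean = %.4f\n",
              x$V_mean, x$V_sd, mean(x$R)))
  invisible(x)
}

#' Nodal information-transfer efficiency
#'
#' Efficiency of node `i` is the mean inverse shortest-path distance to every
#' other node, `E(i) = (1/(N-1)) * sum_{j != i} 1/d(i, j)`, on the unweighted
#' topology, with unreachable pairs contributing 0. Every node of a complete
#' graph has efficiency 1; an isolated node has efficiency 0.
#'
#' @param net An [interaction_network] or igraph with at least 2 nodes.
#' @return An `efficiency_result`: per-node `efficiency` (named) and the
#'   network mean `mu`.
#' @export
nodal_efficiency <- function(net) {
  g <- as_graph(net)
  N <- igraph::vcount(g)
  if (N < 2) stop("network must have at least 2 nodes")
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  eff <- rowSums(inv) / (N - 1)
  names(eff) <- igraph::V(g)$name %||% as.character(seq_len(N))
  structure(list(efficiency = eff, mu = mean(eff)), class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("efficiency_result: %d nodes, mean efficiency mu = %.4f\n",
              length(x$efficiency), x$mu))
  invisible(x)
}

#' Compare vulnerability distributions of two networks
#'
#' Welch's unequal-variance t-test on the per-iteration vulnerability samples
#' of two attack analyses, with the percent change in mean V. At thousands of
#' iterations any real difference yields an extremely small p-value, so the
#' effect size (percent change) is the quantity to interpret; the result
#' carries a note to that effect.
#'
#' @param a,b `attack_result` objects with at least 2 iterations each.
#' @return A `comparison_result`: `statistic`, `p_value`, `mean_a`, `mean_b`,
#'   `percent_change = (mean_a - mean_b)/mean_a * 100`, `test`, `degenerate`.
#' @export
compare_vulnerability <- function(a, b) {
  stopifnot(inherits(a, "attack_result"), inherits(b, "attack_result"))
  if (a$n_iter < 2 || b$n_iter < 2) stop("need >= 2 iterations in each result")
  .welch_compare(a$V, b$V, "Welch t-test on per-iteration vulnerability")
}

#' Compare nodal-efficiency distributions of two networks
#'
#' Welch's t-test on the two per-node efficiency distributions.
#'
#' @param a,b `efficiency_result` objects from networks with >= 3 nodes.
#' @return A `comparison_result` as in [compare_vulnerability()].
#' @export
compare_efficiency <- function(a, b) {
  stopifnot(inherits(a, "efficiency_result"), inherits(b, "efficiency_result"))
  if (length(a$efficiency) < 3 || length(b$efficiency) < 3) {
    stop("each network needs >= 3 nodes")
  }
  .welch_compare(a$efficiency, b$efficiency, "Welch t-test on nodal efficiency")
}

.welch_compare <- function(x, y, test_name) {
  mean_a <- mean(x); mean_b <- mean(y)
  degenerate <- FALSE
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    degenerate <- TRUE
    statistic <- NA_real_
    p_value <- if (isTRUE(all.equal(mean_a, mean_b))) 1 else 0
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
  }
  structure(
    list(
      statistic = statistic, p_value = p_value,
      mean_a = mean_a, mean_b = mean_b,
      percent_change = (mean_a - mean_b) / mean_a * 100,
      test = test_name, degenerate = degenerate,
      note = "with large samples the effect size (percent_change) is more informative than p"
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test, "\n")
  cat(sprintf("  mean_a = %.4g, mean_b = %.4g, change = %.1f%%, p = %.3g%s\n",
              x$mean_a, x$mean_b, x$percent_change, x$p_value,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}
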
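# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph's algorithms where they are the thing
# under test): distances come from a hand-rolled BFS, betweenness from
# explicit enumeration of all shortest paths.

# adjacency list (list of integer vectors) from an interaction_network/igraph
adj_list <- function(net) {
  g <- if (inherits(net, "interaction_network")) net$graph else net
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

# single-source BFS distances; Inf where unreachable
bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (is.infinite(d[u])) {
          d[u] <- d[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# all shortest paths between s and t, enumerated by descending the BFS
# distance field from t back to s; returns a list of vertex vectors
enumerate_shortest_paths <- function(adj, s, t) {
  ds <- bfs_dist(adj, s)
  if (is.infinite(ds[t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == s) {
      paths[[length(paths) + 1]] <<- rev(acc)
      return(invisible())
    }
    for (u in adj[[v]]) if (ds[u] == ds[v] - 1) walk(u, c(acc, u))
  }
  walk(t, t)
  paths
}

# betweenness by brute-force enumeration over unordered pairs: for each pair
# the fraction of its shortest paths passing through each interior vertex
brute_betweenness <- function(net) {
  adj <- adj_list(net)
  n <- length(adj)
  btw <- numeric(n)
  if (n < 3) return(btw)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enumerate_shortest_paths(adj, s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(paths)
      }
    }
  }
  btw
}

# nodal efficiency from the BFS oracle
brute_efficiency <- function(net) {
  adj <- adj_list(net)
  n <- length(adj)
  vapply(seq_len(n), function(i) {
    d <- bfs_dist(adj, i)[-i]
    sum(ifelse(is.finite(d), 1 / d, 0)) / (n - 1)
  }, numeric(1))
}

# exact expected vulnerability of a star graph by enumerating the hub's
# position in the removal order (all positions equally likely)
star_vulnerability_exact <- function(N) {
  Rk <- vapply(seq_len(N), function(k) {
    before <- if (k > 1) sum((N - seq_len(k - 1)) / N) else 0
    after <- (N - k) * (1 / N)
    (before + after) / N
  }, numeric(1))
  0.5 - mean(Rk)
}

# canonical unordered edge-key set of a network
edge_set <- function(net) {
  g <- if (inherits(net, "interaction_network")) net$graph else net
  if (igraph::ecount(g) == 0) return(character(0))
  e <- igraph::ends(g, igraph::E(g))
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|")
}

true_edge_set <- function(truth) {
  if (nrow(truth$true_edges) == 0) return(character(0))
  paste(pmin(truth$true_edges[, 1], truth$true_edges[, 2]),
        pmax(truth$true_edges[, 1], truth$true_edges[, 2]), sep = "|")
}

recovery_metrics <- function(net, truth) {
  est <- edge_set(net)
  tru <- true_edge_set(truth)
  tp <- length(intersect(est, tru))
  c(precision = tp / max(length(est), 1), recall = tp / max(length(tru), 1))
}

# seeded random simple graph as an interaction_network
random_graph <- function(n, p_edge, seed) {
  make_fixture_graph("erdos_renyi", n, p_edge = p_edge, seed = seed)
}

# add k random missing edges to a graph (weight +1), keeping node set
add_random_edges <- function(net, k, seed) {
  g <- net$graph
  comp <- igraph::complementer(g)
  m <- igraph::ecount(comp)
  if (m == 0 || k == 0) return(net)
  set.seed(seed)
  pick <- sample(m, min(k, m))
  ends <- igraph::ends(comp, igraph::E(comp)[pick])
  g2 <- igraph::add_edges(g, t(ends), attr = list(weight = 1))
  interaction_network(g2)
}
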
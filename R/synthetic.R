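#' Fixture graphs with known topology
#'
#' Small named topologies used as oracles for the attack-robustness and
#' efficiency statistics: their vulnerability and efficiency have closed
#' forms or are cheap to enumerate.
#'
#' @param kind One of `"complete"`, `"edgeless"`, `"star"`, `"path"`,
#'   `"erdos_renyi"`, `"barbell"`.
#' @param n Number of nodes (at least 2). For `"barbell"` the nodes split into
#'   two cliques of sizes `ceiling(n/2)` and `floor(n/2)` joined by a single
#'   bridge edge.
#' @param p_edge Edge probability, used only for `"erdos_renyi"`.
#' @param seed RNG seed (only the Erdos-Renyi draw is random).
#' @return An [interaction_network] with node ids `t1..tn` and all edge
#'   weights `+1`.
#' @export
make_fixture_graph <- function(kind, n, p_edge = NULL, seed = NULL) {
  kinds <- c("complete", "edgeless", "star", "path", "erdos_renyi", "barbell")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop("unknown graph kind; expected one of: ", paste(kinds, collapse = ", "))
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  g <- switch(kind,
    complete = igraph::make_full_graph(n),
    edgeless = igraph::make_empty_graph(n, directed = FALSE),
    star     = igraph::make_star(n, mode = "undirected", center = 1),
    path     = igraph::make_ring(n, circular = FALSE),
    erdos_renyi = {
      if (is.null(p_edge) || p_edge < 0 || p_edge > 1) {
        stop("p_edge in [0, 1] is required for erdos_renyi")
      }
      with_seed(seed, igraph::sample_gnp(n, p_edge, directed = FALSE))
    },
    barbell = {
      n1 <- ceiling(n / 2)
      g1 <- igraph::make_full_graph(n1)
      g2 <- igraph::make_full_graph(n - n1)
      gg <- igraph::disjoint_union(g1, g2)
      if (n - n1 >= 1) gg <- igraph::add_edges(gg, c(1, n1 + 1))
      gg
    }
  )
  igraph::V(g)$name <- paste0("t", seq_len(n))
  igraph::V(g)$domain <- "bacteria"
  igraph::V(g)$marker <- "16S"
  if (igraph::ecount(g) > 0) igraph::E(g)$weight <- 1
  interaction_network(g, provenance = list(kind = kind, p_edge = p_edge, seed = seed))
}

#' Ground-truth sparse dependence structure for synthetic communities
#'
#' Draws a sparse symmetric positive-definite precision matrix over `p` taxa:
#' off-diagonal support is sampled uniformly at `edge_density`, nonzero
#' magnitudes are uniform on `magnitude_range` with random signs, and the
#' diagonal is inflated just enough that the minimum eigenvalue reaches
#' `condition_floor`. The nonzero off-diagonal pattern is the set of true
#' conditional-dependence edges that network inference is asked to recover.
#'
#' @param p Number of taxa (>= 4).
#' @param edge_density Fraction of the `p(p-1)/2` pairs carrying an edge
#'   (in (0, 0.5)).
#' @param domain_fractions Named numeric vector over
#'   `c("bacteria","archaea","fungus")` summing to 1. Defaults mirror a
#'   prokaryote-dominated seep community with a substantial fungal minority.
#' @param condition_floor Lower bound imposed on the minimum eigenvalue of the
#'   precision matrix.
#' @param magnitude_range Range of absolute off-diagonal precision entries.
#' @param seed RNG seed.
#' @return A `true_model`: list with `precision` (p x p), `true_edges`
#'   (two-column character matrix of unordered pairs), `domain_of`,
#'   `marker_of`, `seed`.
#' @export
make_true_model <- function(p, edge_density,
                            domain_fractions = c(bacteria = 0.55, archaea = 0.25, fungus = 0.20),
                            condition_floor = 0.2,
                            magnitude_range = c(0.3, 0.6),
                            seed = NULL) {
  p <- as.integer(p)
  if (is.na(p) || p < 4L) stop("p must be an integer >= 4")
  if (edge_density <= 0 || edge_density >= 0.5) stop("edge_density must lie in (0, 0.5)")
  if (abs(sum(domain_fractions) - 1) > 1e-8) stop("domain_fractions must sum to 1")
  if (condition_floor <= 0) stop("condition_floor must be positive")

  with_seed(seed, {
    taxa <- paste0("t", seq_len(p))
    omega <- diag(p)
    pairs <- which(upper.tri(omega), arr.ind = TRUE)
    on <- stats::runif(nrow(pairs)) < edge_density
    vals <- stats::runif(sum(on), magnitude_range[1], magnitude_range[2]) *
      sample(c(-1, 1), sum(on), replace = TRUE)
    sel <- pairs[on, , drop = FALSE]
    omega[sel] <- vals
    omega[sel[, c(2, 1), drop = FALSE]] <- vals

    ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < condition_floor) {
      delta <- condition_floor - ev_min
      if (delta > 100) stop("cannot reach positive definiteness within bounded inflation")
      diag(omega) <- diag(omega) + delta
    }
    dimnames(omega) <- list(taxa, taxa)

    n_dom <- round(p * domain_fractions)
    # rounding drift goes to the largest group
    n_dom[which.max(n_dom)] <- n_dom[which.max(n_dom)] + (p - sum(n_dom))
    domain_of <- rep(names(n_dom), n_dom)[seq_len(p)]
    names(domain_of) <- taxa
    marker_of <- ifelse(domain_of == "fungus", "18S", "16S")
    names(marker_of) <- taxa

    edges <- cbind(taxa[sel[, 1]], taxa[sel[, 2]])
    colnames(edges) <- c("a", "b")
    structure(
      list(precision = omega, true_edges = edges, domain_of = domain_of,
           marker_of = marker_of, seed = seed),
      class = "true_model"
    )
  })
}

#' @export
print.true_model <- function(x, ...) {
  cat("true_model:", nrow(x$precision), "taxa,", nrow(x$true_edges), "true edges\n")
  invisible(x)
}

#' Simulate zero-inflated compositional counts from a known dependence model
#'
#' Logistic-normal-multinomial generator: latent log-abundances are
#' multivariate normal with covariance `latent_scale^2 * solve(truth$precision)`
#' around a fixed per-taxon baseline (drawn once per dataset with standard
#' deviation `mean_log_spread`, giving the persistent orders-of-magnitude
#' unevenness of real communities), mapped through a softmax to per-sample
#' compositions; library sizes are log-normal around `depth_mean`
#' (coefficient of variation 0.3); counts are multinomial at the drawn
#' depth; finally each count is independently zeroed with probability
#' `zero_inflation` (sampling zeros only; no structural absences). Scaling
#' the latent field leaves the partial-correlation structure of
#' `truth$precision` intact.
#'
#' @param truth A `true_model` from [make_true_model()].
#' @param n_samples Number of samples (>= 2).
#' @param depth_mean Mean sequencing depth (reads per sample).
#' @param zero_inflation Probability in `[0, 1)` of zeroing each count.
#' @param latent_scale Standard-deviation multiplier of the latent Gaussian
#'   field (default 2).
#' @param mean_log_spread Standard deviation of the per-taxon baseline
#'   log-abundance (default 1.5); 0 gives an (unrealistically) even
#'   community.
#' @param seed RNG seed.
#' @return A [count_table] annotated from `truth`; the drawn per-sample
#'   depths (pre zero inflation) are stored in attribute `library_depth`.
#' @export
simulate_counts <- function(truth, n_samples, depth_mean = 10000,
                            zero_inflation = 0.1, latent_scale = 2,
                            mean_log_spread = 1.5, seed = NULL) {
  stopifnot(inherits(truth, "true_model"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) stop("n_samples must be >= 2")
  if (zero_inflation < 0 || zero_inflation >= 1) stop("zero_inflation must lie in [0, 1)")
  if (latent_scale <= 0) stop("latent_scale must be positive")

  with_seed(seed, {
    p <- nrow(truth$precision)
    sigma <- chol2inv(chol(truth$precision))
    cs <- chol(sigma)
    mu <- stats::rnorm(p, 0, mean_log_spread)
    z <- latent_scale * (matrix(stats::rnorm(n_samples * p), n_samples, p) %*% cs)
    z <- sweep(z, 2, mu, "+")
    comp <- exp(z - apply(z, 1, max))
    comp <- comp / rowSums(comp)

    cv <- 0.3
    sdlog <- sqrt(log(1 + cv^2))
    depth <- pmax(1L, as.integer(round(stats::rlnorm(
      n_samples, meanlog = log(depth_mean) - sdlog^2 / 2, sdlog = sdlog))))

    counts <- t(vapply(seq_len(n_samples),
                       function(i) stats::rmultinom(1, depth[i], comp[i, ])[, 1],
                       numeric(p)))
    if (zero_inflation > 0) {
      drop <- matrix(stats::runif(length(counts)) < zero_inflation,
                     nrow(counts), ncol(counts))
      counts[drop] <- 0
    }
    rownames(counts) <- paste0("s", seq_len(n_samples))
    colnames(counts) <- names(truth$domain_of)
    out <- count_table(counts, domain = truth$domain_of, marker = truth$marker_of)
    attr(out, "library_depth") <- depth
    out
  })
}

#' Simulate depth-profile metadata with a methane peak in the SMTZ
#'
#' One record per (site, depth slice). The noise-free methane profile is a
#' Gaussian bump centred in the sulfate-methane transition zone (SMTZ) on a
#' small background; sulfate decays monotonically with depth; sulfide and DIC
#' accumulate downward. Multiplicative log-normal noise is added to each.
#'
#' @param sites Character vector of site ids.
#' @param depth_slices_cm List of `c(top, bottom)` depth intervals
#'   (centimetres below sea floor).
#' @param smtz_interval_cm Interval `c(top, bottom)` of the SMTZ; must lie
#'   within the covered depth range.
#' @param methane_peak Peak methane concentration at the SMTZ centre.
#' @param methane_background Background methane away from the SMTZ.
#' @param sulfate_surface Sulfate concentration at the sediment surface.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param control_sites Site ids labelled `"control"` in `seep_status`.
#' @param seed RNG seed.
#' @return A `sample_metadata` data frame (see [validate_metadata()]).
#' @export
simulate_metadata <- function(sites, depth_slices_cm,
                              smtz_interval_cm = c(10, 13),
                              methane_peak = 5,
                              methane_background = 0.2,
                              sulfate_surface = 28,
                              noise_cv = 0.1,
                              control_sites = character(0),
                              seed = NULL) {
  if (length(sites) == 0) stop("at least one site is required")
  if (length(depth_slices_cm) == 0) stop("at least one depth slice is required")
  slices <- do.call(rbind, lapply(depth_slices_cm, function(s) {
    if (length(s) != 2 || s[1] >= s[2]) stop("each depth slice must be c(top, bottom) with top < bottom")
    s
  }))
  covered <- range(slices)
  if (smtz_interval_cm[1] < covered[1] || smtz_interval_cm[2] > covered[2]) {
    stop("smtz_interval_cm must lie within the covered depth range")
  }

  with_seed(seed, {
    center <- mean(smtz_interval_cm)
    width <- max(diff(smtz_interval_cm) / 2, 0.5)
    sdlog <- sqrt(log(1 + noise_cv^2))
    rows <- list()
    k <- 0L
    for (site in sites) {
      for (i in seq_len(nrow(slices))) {
        k <- k + 1L
        top <- slices[i, 1]; bottom <- slices[i, 2]
        mid <- (top + bottom) / 2
        methane0 <- methane_background + methane_peak * exp(-(mid - center)^2 / (2 * width^2))
        sulfate0 <- sulfate_surface * exp(-mid / 20)
        sulfide0 <- 0.1 + 2 * (1 - exp(-mid / 15))
        dic0 <- 2 + 0.15 * mid
        noise <- stats::rlnorm(4, -sdlog^2 / 2, sdlog)
        rows[[k]] <- data.frame(
          sample_id = sprintf("%s_d%02d", site, i),
          site = site,
          depth_top_cm = top, depth_bottom_cm = bottom,
          methane = methane0 * noise[1],
          sulfate = sulfate0 * noise[2],
          sulfide = sulfide0 * noise[3],
          dic = dic0 * noise[4],
          seep_status = if (site %in% control_sites) "control" else "seep",
          stringsAsFactors = FALSE
        )
      }
    }
    meta <- do.call(rbind, rows)
    rownames(meta) <- NULL
    validate_metadata(meta)
    class(meta) <- unique(c("sample_metadata", class(meta)))
    meta
  })
}

#' Plant a two-group balance signal into a count table
#'
#' Assigns balanced binary response labels to the samples and shifts the
#' planted taxa by `exp(effect_size)`: numerator taxa are multiplied up in
#' `"high"` samples, denominator taxa in `"low"` samples, and counts
#' re-rounded to integers. The returned truth record is the oracle for
#' balance-selection recovery tests.
#'
#' @param counts A [count_table].
#' @param numerator_taxa,denominator_taxa Disjoint non-empty taxon id sets.
#' @param effect_size Non-negative log-ratio shift between response classes.
#' @param seed RNG seed (label assignment).
#' @return List with `counts` (modified [count_table]) and `signal`
#'   (`planted_signal`: the two groups, the effect size, and the per-sample
#'   `response` factor with levels `low`, `high`).
#' @export
plant_balance_signal <- function(counts, numerator_taxa, denominator_taxa,
                                 effect_size, seed = NULL) {
  stopifnot(inherits(counts, "count_table"))
  if (length(numerator_taxa) == 0 || length(denominator_taxa) == 0) {
    stop("numerator and denominator groups must be non-empty")
  }
  if (length(intersect(numerator_taxa, denominator_taxa)) > 0) {
    stop("numerator and denominator groups overlap")
  }
  absent <- setdiff(c(numerator_taxa, denominator_taxa), taxon_ids(counts))
  if (length(absent)) stop("taxa not in table: ", paste(absent, collapse = ", "))
  if (effect_size < 0) stop("effect_size must be >= 0")

  with_seed(seed, {
    n <- nrow(counts$counts)
    high <- sample(n, floor(n / 2))
    response <- factor(ifelse(seq_len(n) %in% high, "high", "low"),
                       levels = c("low", "high"))
    mat <- counts$counts
    mult <- exp(effect_size)
    mat[response == "high", numerator_taxa] <-
      round(mat[response == "high", numerator_taxa, drop = FALSE] * mult)
    mat[response == "low", denominator_taxa] <-
      round(mat[response == "low", denominator_taxa, drop = FALSE] * mult)
    out <- count_table(mat, domain = counts$domain, marker = counts$marker,
                       taxonomy = counts$taxonomy)
    names(response) <- sample_ids(out)
    signal <- structure(
      list(numerator_taxa = numerator_taxa, denominator_taxa = denominator_taxa,
           effect_size = effect_size, response = response),
      class = "planted_signal"
    )
    list(counts = out, signal = signal)
  })
}
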
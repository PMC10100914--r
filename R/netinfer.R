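#' Parameters for sparse network inference
#'
#' Bundles the tuning parameters of penalized neighborhood selection with
#' StARS stability selection and the optional low-rank latent-variable
#' adjustment. The defaults (`nlambda = 20`, `lambda_min_ratio = 0.005`,
#' `stars_threshold = 0.05`, `n_reps = 20`) are the standard settings for
#' cross-domain co-occurrence inference on amplicon data.
#'
#' @param nlambda Length of the log-spaced penalty path.
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`.
#' @param stars_threshold StARS edge-instability threshold.
#' @param n_reps Number of StARS subsamples.
#' @param subsample_size Function of `n` giving the subsample size (drawn
#'   without replacement); default `floor(10 * sqrt(n))`, falling back to
#'   `floor(0.8 * n)` when that would exceed 80% of the samples — the
#'   standard stability-selection rule for small cohorts.
#' @param latent_rank_max Maximum latent rank to consider; 0 disables the
#'   latent-variable adjustment.
#' @param ebic_gamma Extended-BIC gamma used for latent rank selection.
#' @param seed Master seed; per-subsample seeds are derived deterministically.
#' @return A `netinfer_params` list.
#' @export
netinfer_params <- function(nlambda = 20, lambda_min_ratio = 0.005,
                            stars_threshold = 0.05, n_reps = 20,
                            subsample_size = function(n) min(floor(10 * sqrt(n)), floor(0.8 * n)),
                            latent_rank_max = 0, ebic_gamma = 0.5, seed = 1) {
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1) stop("lambda_min_ratio must lie in (0, 1)")
  if (stars_threshold <= 0 || stars_threshold >= 1) stop("stars_threshold must lie in (0, 1)")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (nlambda < 2) stop("nlambda must be >= 2")
  if (latent_rank_max < 0) stop("latent_rank_max must be >= 0")
  structure(
    list(nlambda = as.integer(nlambda), lambda_min_ratio = lambda_min_ratio,
         stars_threshold = stars_threshold, n_reps = as.integer(n_reps),
         subsample_size = subsample_size,
         latent_rank_max = as.integer(latent_rank_max),
         ebic_gamma = ebic_gamma, seed = as.integer(seed)),
    class = "netinfer_params"
  )
}

# Neighborhood-selection path: per-node lasso regressions of each
# (standardized) column on all others across a decreasing lambda path.
# Returns beta[j, k, l] = coefficient of predictor k in the regression of
# node j at lambda l, and optionally per-node residual sums of squares.
.mb_fit <- function(X, lambdas, want_rss = FALSE) {
  n <- nrow(X); p <- ncol(X); K <- length(lambdas)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate (constant) columns: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Xs <- scale(X)
  beta <- array(0, dim = c(p, p, K))
  rss <- if (want_rss) matrix(NA_real_, p, K) else NULL
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(Xs[, -j, drop = FALSE], Xs[, j],
                          family = "gaussian", lambda = lambdas,
                          standardize = FALSE, intercept = FALSE)
    bj <- as.matrix(fit$beta)  # (p-1) x K' (glmnet may stop early)
    Kf <- ncol(bj)
    beta[j, -j, seq_len(Kf)] <- bj
    if (Kf < K) for (l in (Kf + 1):K) beta[j, -j, l] <- bj[, Kf]
    if (want_rss) {
      pred <- Xs[, -j, drop = FALSE] %*% beta[j, -j, , drop = TRUE]
      rss[j, ] <- colSums((Xs[, j] - pred)^2)
    }
  }
  list(beta = beta, rss = rss, n = n, p = p, lambdas = lambdas)
}

# Symmetric edge-indicator array (p x p x K) under the union ("or") rule.
.mb_adjacency <- function(beta) {
  sel <- beta != 0
  sel | aperm(sel, c(2, 1, 3))
}

# Extended BIC of each model along the path, from the Gaussian
# pseudo-likelihood of the per-node regressions and the selected edge count.
.mb_ebic <- function(fit, gamma) {
  adj <- .mb_adjacency(fit$beta)
  K <- length(fit$lambdas)
  ut <- upper.tri(matrix(0, fit$p, fit$p))
  vapply(seq_len(K), function(l) {
    n_edges <- sum(adj[, , l][ut])
    fit$n * sum(log(pmax(fit$rss[, l], 1e-12) / fit$n)) +
      n_edges * (log(fit$n) + 4 * gamma * log(fit$p))
  }, numeric(1))
}

#' StARS stability selection along a penalty path
#'
#' Builds a log-spaced path of `nlambda` penalties from `lambda_max` (the
#' largest absolute off-diagonal empirical correlation) down to
#' `lambda_max * lambda_min_ratio`, runs neighborhood selection on `n_reps`
#' random subsamples of size `subsample_size(n)` (without replacement), and
#' records each edge's selection frequency at every penalty. The total
#' instability at a penalty is the mean over all node pairs of
#' `2 * f * (1 - f)`; after monotonizing the instability from the sparse end
#' (running maximum along decreasing lambda), the smallest penalty whose
#' monotonized instability stays at or below `stars_threshold` is selected —
#' the densest graph that is still stable under subsampling.
#'
#' @param clr A [clr_matrix] or numeric matrix (samples x taxa).
#' @param params A [netinfer_params].
#' @return A `stars_path` list: `lambdas`, `freq` (p x p x nlambda symmetric
#'   selection frequencies), `instability`, `monotonized_instability`,
#'   `selected_index`, `lambda_selected`, `subsample_size`.
#' @export
stars_path <- function(clr, params = netinfer_params()) {
  X <- unclass(as.matrix(clr))
  n <- nrow(X); p <- ncol(X)
  if (p < 3) stop("need at least 3 taxa")
  b <- params$subsample_size(n)
  if (b > n) stop("subsample size (", b, ") exceeds the number of samples (", n, ")")
  if (b < 3) stop("subsample size too small")

  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate (constant) columns: ", paste(colnames(X)[sds == 0], collapse = ", "))
  }
  S <- abs(stats::cor(X))
  diag(S) <- 0
  lambda_max <- max(S)
  if (lambda_max <= 0) lambda_max <- 1e-3
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * params$lambda_min_ratio),
                     length.out = params$nlambda))

  freq <- array(0, dim = c(p, p, params$nlambda))
  with_seed(params$seed, {
    for (rep in seq_len(params$n_reps)) {
      set.seed(derive_seed(params$seed, rep))
      idx <- sample.int(n, b)
      Xi <- X[idx, , drop = FALSE]
      if (any(apply(Xi, 2, stats::sd) == 0)) {
        # a subsample can be degenerate even when the data are not; jitter
        # minimally to keep the path defined
        const <- apply(Xi, 2, stats::sd) == 0
        Xi[, const] <- Xi[, const] + stats::rnorm(sum(const) * b, sd = 1e-8)
      }
      fit <- .mb_fit(Xi, lambdas)
      freq <- freq + .mb_adjacency(fit$beta)
    }
  })
  freq <- freq / params$n_reps

  ut <- upper.tri(matrix(0, p, p))
  instability <- vapply(seq_len(params$nlambda), function(l) {
    f <- freq[, , l][ut]
    mean(2 * f * (1 - f))
  }, numeric(1))
  monotonized <- cummax(instability)
  ok <- which(monotonized <= params$stars_threshold)
  selected_index <- if (length(ok)) max(ok) else 1L

  structure(
    list(lambdas = lambdas, freq = freq, instability = instability,
         monotonized_instability = monotonized,
         selected_index = selected_index,
         lambda_selected = lambdas[selected_index],
         subsample_size = b, taxa = colnames(X)),
    class = "stars_path"
  )
}

#' Latent-variable rank selection by principal-component removal
#'
#' Accounts for dense latent effects (sequencing depth, environmental
#' gradients) that would otherwise masquerade as biological edges: for each
#' candidate rank `r` in `0..latent_rank_max`, the top `r` principal
#' components are removed from the column-centered CLR matrix, a
#' neighborhood-selection path is fitted to the residual, and each fit is
#' scored by the extended BIC (Gaussian pseudo-likelihood plus an
#' `ebic_gamma`-weighted model-size penalty, counting both the selected
#' edges and the `p * r` factor loadings so that removing components must
#' pay for itself). The rank minimizing the eBIC wins and its adjusted
#' matrix is returned.
#'
#' @param clr A [clr_matrix] or numeric matrix.
#' @param params A [netinfer_params]; `latent_rank_max = 0` is an identity
#'   pass-through.
#' @return List: `rank` (chosen r), `adjusted` (matrix with the top-r PCs
#'   removed), `ebic` (best eBIC per candidate rank, or `NULL` when
#'   disabled).
#' @export
latent_rank_select <- function(clr, params = netinfer_params()) {
  X <- unclass(as.matrix(clr))
  if (params$latent_rank_max == 0) {
    return(list(rank = 0L, adjusted = X, ebic = NULL))
  }
  n <- nrow(X); p <- ncol(X)
  rmax <- params$latent_rank_max
  if (rmax >= min(n, p)) stop("latent_rank_max must be < min(n_samples, n_taxa)")

  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = rmax, nv = rmax)

  S <- abs(stats::cor(X)); diag(S) <- 0
  lambda_max <- max(max(S), 1e-3)
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * params$lambda_min_ratio),
                     length.out = params$nlambda))

  ebic_best <- numeric(rmax + 1)
  adjusted_list <- vector("list", rmax + 1)
  for (r in 0:rmax) {
    Xr <- if (r == 0) Xc else {
      Xc - sv$u[, seq_len(r), drop = FALSE] %*%
        (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
    }
    colnames(Xr) <- colnames(X)
    fit <- .mb_fit(Xr, lambdas, want_rss = TRUE)
    rank_penalty <- r * p * log(n)
    ebic_best[r + 1] <- min(.mb_ebic(fit, params$ebic_gamma)) + rank_penalty
    adjusted_list[[r + 1]] <- Xr
  }
  rank <- which.min(ebic_best) - 1L
  list(rank = rank, adjusted = adjusted_list[[rank + 1]], ebic = ebic_best)
}

#' Infer a signed cross-domain interaction network
#'
#' The full inference stack: latent-rank adjustment ([latent_rank_select()]),
#' StARS penalty selection ([stars_path()]) on the adjusted matrix, then a
#' refit of neighborhood selection on the full data at the selected penalty.
#' The two directed coefficients of each node pair are symmetrized by keeping
#' the one of larger magnitude (ties: the coefficient from the regression
#' whose response node is lexicographically smaller); the kept coefficient's
#' sign and value become the edge's signed pseudocorrelation-like weight.
#' Isolated nodes are dropped from the final graph but counted in
#' `n_input_taxa`.
#'
#' @param clr A [clr_matrix] or numeric matrix (samples x taxa).
#' @param params A [netinfer_params].
#' @param domain,marker,taxonomy Optional named per-taxon annotation carried
#'   onto the nodes.
#' @return An [interaction_network]; edges carry `weight` (signed
#'   coefficient) and `stability` (StARS selection frequency at the chosen
#'   penalty). An empty selection yields a zero-edge network with
#'   `provenance$empty = TRUE` and a warning.
#' @export
infer_network <- function(clr, params = netinfer_params(),
                          domain = NULL, marker = NULL, taxonomy = NULL) {
  X <- unclass(as.matrix(clr))
  taxa <- colnames(X) %||% paste0("t", seq_len(ncol(X)))
  colnames(X) <- taxa

  lr <- latent_rank_select(X, params)
  sp <- stars_path(lr$adjusted, params)

  fit <- .mb_fit(lr$adjusted, sp$lambdas)
  B <- fit$beta[, , sp$selected_index]
  p <- ncol(X)
  W <- matrix(0, p, p, dimnames = list(taxa, taxa))
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      bjk <- B[j, k]  # response j (lexicographic order of construction: j < k)
      bkj <- B[k, j]
      w <- if (abs(bjk) > abs(bkj)) bjk
      else if (abs(bkj) > abs(bjk)) bkj
      else if (taxa[j] <= taxa[k]) bjk else bkj
      W[j, k] <- W[k, j] <- w
    }
  }

  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  igraph::V(g)$domain <- if (!is.null(domain)) unname(domain[taxa]) else NA_character_
  igraph::V(g)$marker <- if (!is.null(marker)) unname(marker[taxa]) else NA_character_
  if (!is.null(taxonomy)) igraph::V(g)$taxonomy <- unname(taxonomy[taxa])
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    stab <- sp$freq[, , sp$selected_index]
    dimnames(stab) <- list(taxa, taxa)
    igraph::E(g)$stability <- stab[ends]
  }
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])

  empty <- igraph::ecount(g) == 0
  if (empty) warning("selected network has no edges")
  prov <- list(
    params = params, lambda_selected = sp$lambda_selected,
    lambda_index = sp$selected_index, latent_rank = lr$rank,
    instability = sp$instability, subsample_size = sp$subsample_size,
    empty = empty
  )
  interaction_network(g, provenance = prov, n_input_taxa = p)
}
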
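#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: 30% prevalence
#' and 1e-4 relative-abundance filters, CLR pseudocount 1, the
#' [netinfer_params()] defaults (nlambda 20, lambda-min ratio 0.005, StARS
#' threshold 0.05, 20 subsamples), 10,000 attack iterations, keystone
#' percentile 0.80 and core percentile 0.50 with a 3-edge minimum, 5-fold
#' balance cross-validation with a 30% signature threshold, and an SMTZ of
#' 10-13 cm below sea floor. `balance_n_repeats` defaults to 100 (500
#' validation steps), a desk-scale stand-in for the 2000-repeat (10,000-step)
#' screen; raise it for production runs.
#'
#' @param input_dir Directory for [read_bundle()], or `NULL` to simulate a
#'   community from `sim`.
#' @param sim List of synthetic-community settings used when `input_dir` is
#'   `NULL`: `p`, `edge_density`, `n_samples`, `depth_mean`,
#'   `zero_inflation`.
#' @param variants Named list of domain subsets to infer networks for.
#' @param min_prevalence,min_mean_relabund Taxon filter thresholds.
#' @param pseudocount CLR and balance pseudocount.
#' @param netinfer A [netinfer_params] object.
#' @param attack_n_iter Random-attack iterations per network.
#' @param keystone_percentile,core_percentile,core_min_edges Topology
#'   thresholds.
#' @param balance_n_folds,balance_n_repeats,balance_max_size,signature_threshold
#'   Balance-selection settings.
#' @param smtz_interval_cm SMTZ depth interval for methane discretization.
#' @param seed Master seed for the whole run.
#' @return A `seepnet_config` list.
#' @export
seepnet_config <- function(input_dir = NULL,
                           sim = list(p = 60, edge_density = 0.05, n_samples = 130,
                                      depth_mean = 10000, zero_inflation = 0.1),
                           variants = list(
                             BAF = c("bacteria", "archaea", "fungus"),
                             BA = c("bacteria", "archaea"),
                             BF = c("bacteria", "fungus"),
                             B = "bacteria",
                             F = "fungus"
                           ),
                           min_prevalence = 0.30, min_mean_relabund = 1e-4,
                           pseudocount = 1,
                           netinfer = netinfer_params(),
                           attack_n_iter = 10000,
                           keystone_percentile = 0.80,
                           core_percentile = 0.50, core_min_edges = 3,
                           balance_n_folds = 5, balance_n_repeats = 100,
                           balance_max_size = 8,
                           signature_threshold = 0.30,
                           smtz_interval_cm = c(10, 13),
                           seed = 1) {
  structure(
    list(input_dir = input_dir, sim = sim, variants = variants,
         min_prevalence = min_prevalence, min_mean_relabund = min_mean_relabund,
         pseudocount = pseudocount, netinfer = netinfer,
         attack_n_iter = attack_n_iter,
         keystone_percentile = keystone_percentile,
         core_percentile = core_percentile, core_min_edges = core_min_edges,
         balance_n_folds = balance_n_folds, balance_n_repeats = balance_n_repeats,
         balance_max_size = balance_max_size,
         signature_threshold = signature_threshold,
         smtz_interval_cm = smtz_interval_cm, seed = as.integer(seed)),
    class = "seepnet_config"
  )
}

.config_hash <- function(config) {
  flat <- utils::capture.output(utils::str(config, digits.d = 15, vec.len = 1e6))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(flat, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates: simulate-or-load, taxon filtering, per-marker CLR,
#' independent network inference for each domain variant (BAF, BA, BF, B,
#' F), centralities/keystones/core on the first variant, random-attack
#' robustness plus nodal efficiency with pairwise comparisons against the
#' first variant, and balance selection of fungal taxa against the
#' discretized methane response. All tables (TSV), networks (GraphML + edge
#' list), JSON summaries and a run log (master seed, config hash, package
#' and R versions) are written to `out_dir`. A failing stage aborts with the
#' stage name; outputs of completed stages remain on disk.
#'
#' @param config A [seepnet_config].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory results (`counts`, `metadata`,
#'   `response`, `networks`, `centralities`, `keystones`, `core`, `attack`,
#'   `efficiency`, `comparisons`, `balance_report`, `signature`).
#' @export
run_pipeline <- function(config = seepnet_config(), out_dir) {
  stopifnot(inherits(config, "seepnet_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  notices <- character(0)
  res <- list()
  say <- function(...) message("[seepnet] ", ...)

  run_stage <- function(name, expr) {
    stage <- name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", out_dir, ")", call. = FALSE)
    })
  }

  ## --- input ---------------------------------------------------------------
  run_stage("input", {
    if (!is.null(config$input_dir)) {
      bundle <- read_bundle(config$input_dir)
      res$counts <- bundle$counts
      res$metadata <- bundle$metadata
    } else {
      s <- config$sim
      truth <- make_true_model(s$p, s$edge_density, seed = derive_seed(config$seed, 101))
      counts <- simulate_counts(truth, s$n_samples, depth_mean = s$depth_mean,
                                zero_inflation = s$zero_inflation,
                                seed = derive_seed(config$seed, 102))
      n_sites <- 4
      slices <- lapply(seq_len(ceiling(s$n_samples / n_sites)),
                       function(i) c((i - 1) * 3, i * 3))
      meta <- simulate_metadata(paste0("site", seq_len(n_sites)), slices,
                                smtz_interval_cm = config$smtz_interval_cm,
                                seed = derive_seed(config$seed, 103))
      meta <- meta[seq_len(min(nrow(meta), s$n_samples)), , drop = FALSE]
      # align metadata rows to the simulated samples
      meta$sample_id <- sample_ids(counts)[seq_len(nrow(meta))]
      res$counts <- counts
      res$metadata <- meta
      res$truth <- truth
      write_true_model(truth, file.path(out_dir, "true_model.json"))
    }
    write_bundle(res$counts, res$metadata, file.path(out_dir, "input"))
  })
  say("input: ", nrow(res$counts$counts), " samples x ", ncol(res$counts$counts), " taxa")

  ## --- preprocess ----------------------------------------------------------
  run_stage("filter", {
    res$filtered <- filter_taxa(res$counts, config$min_prevalence,
                                 config$min_mean_relabund)
  })
  say("filter: ", ncol(res$filtered$counts), " taxa retained (",
      attr(res$filtered, "removed")["total"], " removed)")

  run_stage("response", {
    res$response <- discretize_methane(res$metadata,
                                        smtz_interval_cm = config$smtz_interval_cm)
  })

  ## --- network inference per variant --------------------------------------
  run_stage("infer", {
    nets <- list()
    for (vn in names(config$variants)) {
      doms <- intersect(config$variants[[vn]], unique(res$filtered$domain))
      if (length(doms) == 0) {
        notices <- c(notices, paste0("variant ", vn, ": no taxa, skipped"))
        next
      }
      sub <- subset_domains(res$filtered, doms)
      if (ncol(sub$counts) < 3) {
        notices <- c(notices, paste0("variant ", vn, ": fewer than 3 taxa, skipped"))
        next
      }
      clr <- clr_transform(sub, config$pseudocount)
      params <- config$netinfer
      params$seed <- derive_seed(config$seed, 200 + match(vn, names(config$variants)))
      net <- suppressWarnings(
        infer_network(clr, params, domain = sub$domain, marker = sub$marker,
                      taxonomy = sub$taxonomy))
      nets[[vn]] <- net
      write_network(net, file.path(out_dir, paste0("network_", vn, ".graphml")), "graphml")
      write_network(net, file.path(out_dir, paste0("network_", vn, ".tsv")), "edgelist")
      write_network(net, file.path(out_dir, paste0("network_", vn, ".json")), "json")
    }
    res$networks <- nets
  })
  say("infer: ", length(res$networks), " network(s): ",
      paste(sprintf("%s (%d edges)", names(res$networks),
                    vapply(res$networks, function(x) igraph::ecount(x$graph), numeric(1))),
            collapse = ", "))

  usable <- names(res$networks)[vapply(res$networks, function(x) {
    igraph::ecount(x$graph) > 0 && igraph::vcount(x$graph) >= 3
  }, TRUE)]

  ## --- topology on the primary (first) variant -----------------------------
  run_stage("topology", {
    if (length(usable) > 0) {
      main <- res$networks[[usable[1]]]
      ct <- compute_centralities(main)
      res$centralities <- ct
      utils::write.table(ct, file.path(out_dir, "centralities.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$keystones <- keystone_nodes(ct, config$keystone_percentile)
      utils::write.table(res$keystones$flags, file.path(out_dir, "keystones.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$core <- suppressWarnings(
        core_network(main, config$core_percentile, config$core_min_edges))
      write_network(res$core, file.path(out_dir, "core_network.graphml"), "graphml")
    } else {
      notices <- c(notices, "topology: no usable network, skipped")
    }
  })

  ## --- perturbation --------------------------------------------------------
  run_stage("perturbation", {
    attack <- list(); eff <- list()
    for (vn in usable) {
      g <- res$networks[[vn]]
      attack[[vn]] <- attack_robustness(g, n_iter = config$attack_n_iter,
                                        seed = derive_seed(config$seed, 300 + match(vn, usable)))
      eff[[vn]] <- nodal_efficiency(g)
    }
    res$attack <- attack
    res$efficiency <- eff
    if (length(attack) >= 1) {
      summ <- data.frame(
        variant = names(attack),
        n_nodes = vapply(attack, function(a) as.integer(a$n_nodes), 1L),
        V_mean = vapply(attack, function(a) a$V_mean, 1),
        V_sd = vapply(attack, function(a) a$V_sd, 1),
        efficiency_mu = vapply(eff[names(attack)], function(e) e$mu, 1),
        stringsAsFactors = FALSE
      )
      utils::write.table(summ, file.path(out_dir, "attack_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    comps <- list()
    if (length(usable) >= 2) {
      for (vn in usable[-1]) {
        comps[[paste0(usable[1], "_vs_", vn)]] <- list(
          vulnerability = compare_vulnerability(attack[[usable[1]]], attack[[vn]]),
          efficiency = compare_efficiency(eff[[usable[1]]], eff[[vn]])
        )
      }
    } else {
      notices <- c(notices, "comparisons: fewer than 2 usable networks, skipped")
    }
    res$comparisons <- comps
  })

  ## --- balances ------------------------------------------------------------
  run_stage("balances", {
    if ("fungus" %in% res$filtered$domain && nlevels(droplevels(res$response)) == 2) {
      fungal <- subset_domains(res$filtered, "fungus")
      shared <- intersect(sample_ids(fungal), names(res$response))
      rep_b <- greedy_balance_cv(
        fungal$counts[shared, , drop = FALSE],
        res$response[shared],
        n_folds = config$balance_n_folds, n_repeats = config$balance_n_repeats,
        max_size = config$balance_max_size, pseudocount = config$pseudocount,
        seed = derive_seed(config$seed, 400))
      res$balance_report <- rep_b
      res$signature <- signature_taxa(rep_b, config$signature_threshold)
      freq_df <- data.frame(taxon = names(rep_b$freq), frequency = unname(rep_b$freq),
                            signature = names(rep_b$freq) %in% res$signature,
                            stringsAsFactors = FALSE)
      utils::write.table(freq_df, file.path(out_dir, "balance_frequencies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      notices <- c(notices, "balances: no fungal taxa or single-class response, skipped")
    }
  })

  ## --- summary + log -------------------------------------------------------
  run_stage("summary", {
    hash <- .config_hash(config)
    summary <- list(
      seed = config$seed,
      config_hash = hash,
      n_samples = nrow(res$counts$counts),
      n_taxa_input = ncol(res$counts$counts),
      n_taxa_filtered = ncol(res$filtered$counts),
      networks = lapply(res$networks, function(x) list(
        n_input_taxa = x$n_input_taxa, n_connected = x$n_connected,
        n_edges = igraph::ecount(x$graph),
        lambda_selected = x$provenance$lambda_selected,
        latent_rank = x$provenance$latent_rank)),
      V_mean = lapply(res$attack, function(a) a$V_mean),
      efficiency_mu = lapply(res$efficiency, function(e) e$mu),
      n_keystones = if (!is.null(res$keystones)) length(res$keystones$keystone_ids),
      signature_taxa = res$signature,
      notices = notices
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    log <- c(
      paste0("seepnet ", as.character(utils::packageVersion("seepnet"))),
      paste0("R ", R.version$major, ".", R.version$minor),
      paste0("master seed: ", config$seed),
      paste0("config hash: ", hash),
      notices
    )
    writeLines(log, file.path(out_dir, "run_log.txt"))
  })
  if (length(notices)) for (nt in notices) say(nt)
  invisible(res)
}
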
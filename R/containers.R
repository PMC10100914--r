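#' Construct a sample-by-taxon count table
#'
#' The central data container of the package: a non-negative integer matrix of
#' marker-gene counts with samples as rows and taxa (ASVs) as columns, plus
#' per-taxon annotation of domain (bacteria, archaea, fungus, other) and
#' marker gene (16S or 18S).
#'
#' @param counts Non-negative numeric matrix, samples as rows, taxa as
#'   columns. Row and column names are used as sample and taxon identifiers;
#'   unnamed dimensions get `s1..sn` / `t1..tp`.
#' @param domain Character vector (one of `"bacteria"`, `"archaea"`,
#'   `"fungus"`, `"other"`), either named by taxon id or in column order.
#' @param marker Character vector (`"16S"` or `"18S"`), named or in column
#'   order. Defaults to `"18S"` for fungi and `"16S"` otherwise.
#' @param taxonomy Optional character vector of lineage strings per taxon.
#' @return An object of class `count_table`: a list with elements `counts`,
#'   `domain`, `marker`, `taxonomy`.
#' @export
count_table <- function(counts, domain, marker = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("t", seq_len(ncol(counts)))
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  taxa <- colnames(counts)
  domain <- .align_annotation(domain, taxa, "domain")
  ok <- domain %in% c("bacteria", "archaea", "fungus", "other")
  if (!all(ok)) stop("unknown domain label(s): ", paste(unique(domain[!ok]), collapse = ", "))
  if (is.null(marker)) marker <- ifelse(domain == "fungus", "18S", "16S")
  marker <- .align_annotation(marker, taxa, "marker")
  if (!all(marker %in% c("16S", "18S"))) stop("marker must be '16S' or '18S'")
  if (!is.null(taxonomy)) taxonomy <- .align_annotation(taxonomy, taxa, "taxonomy")
  structure(
    list(counts = counts, domain = domain, marker = marker, taxonomy = taxonomy),
    class = "count_table"
  )
}

.align_annotation <- function(x, taxa, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(taxa, names(x))
    if (length(missing)) {
      stop("missing ", what, " annotation for taxa: ", paste(missing, collapse = ", "))
    }
    x <- x[taxa]
  } else if (length(x) == 1L) {
    x <- rep(x, length(taxa))
    names(x) <- taxa
  } else {
    if (length(x) != length(taxa)) {
      stop(what, " annotation length (", length(x), ") does not match taxon count (",
           length(taxa), ")")
    }
    names(x) <- taxa
  }
  x
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  cat("  domains:", paste(sprintf("%s=%d", names(table(x$domain)), table(x$domain)),
                          collapse = ", "), "\n")
  cat("  markers:", paste(sprintf("%s=%d", names(table(x$marker)), table(x$marker)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Sample and taxon identifiers of a count table
#' @param x A `count_table`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname sample_ids
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' Subset a count table to a set of taxa
#' @param x A `count_table`.
#' @param taxa Character vector of taxon ids to keep (order preserved).
#' @return A `count_table` on the selected taxa; samples unchanged.
#' @export
keep_taxa <- function(x, taxa) {
  stopifnot(inherits(x, "count_table"))
  missing <- setdiff(taxa, taxon_ids(x))
  if (length(missing)) stop("unknown taxa: ", paste(missing, collapse = ", "))
  count_table(
    x$counts[, taxa, drop = FALSE],
    domain = x$domain[taxa],
    marker = x$marker[taxa],
    taxonomy = if (!is.null(x$taxonomy)) x$taxonomy[taxa]
  )
}

#' Validate per-sample metadata
#'
#' Metadata is held as a plain data frame with one row per sample: `sample_id`,
#' `site`, depth interval (`depth_top_cm`, `depth_bottom_cm`, centimetres below
#' sea floor) and porewater chemistry columns (`methane`, `sulfate`, `sulfide`,
#' `dic`; units as provided, `NA` allowed) plus `seep_status`
#' (`"seep"`/`"control"`).
#'
#' @param meta A data frame.
#' @return The validated data frame (invisibly classed `sample_metadata`).
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "site", "depth_top_cm", "depth_bottom_cm")
  missing <- setdiff(need, names(meta))
  if (length(missing)) stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  bad <- meta$depth_top_cm >= meta$depth_bottom_cm
  if (any(bad, na.rm = TRUE)) {
    stop("depth_top_cm must be < depth_bottom_cm (rows: ",
         paste(which(bad), collapse = ", "), ")")
  }
  for (v in intersect(c("methane", "sulfate", "sulfide", "dic"), names(meta))) {
    if (any(meta[[v]] < 0, na.rm = TRUE)) stop("negative values in ", v)
  }
  class(meta) <- unique(c("sample_metadata", class(meta)))
  invisible(meta)
}

#' Construct a CLR-transformed abundance matrix
#'
#' @param values Real matrix (samples x taxa), rows summing to zero within
#'   each marker block.
#' @param pseudocount The pseudocount that was added before the log.
#' @param marker_blocks Named list mapping marker to the taxon ids transformed
#'   jointly.
#' @return A `clr_matrix`: the matrix with attributes `pseudocount` and
#'   `marker_blocks`.
#' @export
clr_matrix <- function(values, pseudocount, marker_blocks) {
  structure(values, pseudocount = pseudocount, marker_blocks = marker_blocks,
            class = c("clr_matrix", "matrix"))
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat("clr_matrix:", nrow(x), "samples x", ncol(x), "taxa; pseudocount",
      attr(x, "pseudocount"), "\n")
  blocks <- attr(x, "marker_blocks")
  cat("  marker blocks:",
      paste(sprintf("%s (%d taxa)", names(blocks), lengths(blocks)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Construct an interaction network
#'
#' A signed, weighted, undirected graph over taxa. The graph itself is an
#' [igraph::igraph] with vertex attributes `domain` and `marker` and edge
#' attributes `weight` (signed pseudocorrelation-like coefficient) and,
#' when inferred, `stability` (StARS selection frequency). Provenance of the
#' inference (parameters, selected penalty, latent rank) travels alongside.
#'
#' @param graph An undirected igraph with a `weight` edge attribute.
#' @param provenance Optional list describing how the network was produced.
#' @param n_input_taxa Number of taxa given to the inference (before dropping
#'   isolated nodes); defaults to the current vertex count.
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(graph, provenance = NULL, n_input_taxa = NULL) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) stop("interaction networks are undirected")
  if (igraph::any_multiple(graph) || any(igraph::which_loop(graph))) {
    stop("interaction networks must be simple (no loops or multi-edges)")
  }
  if (igraph::ecount(graph) > 0 && is.null(igraph::E(graph)$weight)) {
    igraph::E(graph)$weight <- 1
  }
  w <- igraph::E(graph)$weight
  if (length(w) && any(!is.finite(w) | w == 0)) stop("edge weights must be finite and nonzero")
  structure(
    list(
      graph = graph,
      provenance = provenance,
      n_input_taxa = if (is.null(n_input_taxa)) igraph::vcount(graph) else n_input_taxa,
      n_connected = sum(igraph::degree(graph) > 0)
    ),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  g <- x$graph
  cat("interaction_network:", igraph::vcount(g), "nodes,", igraph::ecount(g), "edges\n")
  cat("  input taxa:", x$n_input_taxa, "| connected:", x$n_connected, "\n")
  if (!is.null(x$provenance$lambda_selected)) {
    cat("  selected lambda:", signif(x$provenance$lambda_selected, 4),
        "| latent rank:", x$provenance$latent_rank %||% 0, "\n")
  }
  invisible(x)
}

# Coerce igraph or interaction_network to igraph for graph algorithms.
as_graph <- function(net) {
  if (inherits(net, "interaction_network")) return(net$graph)
  if (igraph::is_igraph(net)) return(net)
  stop("expected an interaction_network or igraph object")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
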
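#' Read a count/taxonomy/metadata bundle from tab-separated files
#'
#' Expects three TSV files: `counts.tsv` (samples as rows, taxa as columns,
#' first column `sample_id`), `taxonomy.tsv` (columns `taxon_id`, `domain`,
#' `marker`, optional `lineage`) and `metadata.tsv` (one row per sample, see
#' [validate_metadata()]). Identifier consistency is enforced: every taxon in
#' the count table must be annotated, duplicates are errors, and any
#' count-table samples missing from the metadata (or vice versa) are
#' reported.
#'
#' @param dir Directory holding the three files, or `NULL` when all three
#'   paths are given explicitly.
#' @param counts_file,taxonomy_file,metadata_file Explicit paths, overriding
#'   `dir`.
#' @return List with `counts` (a [count_table]) and `metadata`
#'   (`sample_metadata` data frame).
#' @export
read_bundle <- function(dir = NULL, counts_file = NULL, taxonomy_file = NULL,
                        metadata_file = NULL) {
  counts_file <- counts_file %||% file.path(dir, "counts.tsv")
  taxonomy_file <- taxonomy_file %||% file.path(dir, "taxonomy.tsv")
  metadata_file <- metadata_file %||% file.path(dir, "metadata.tsv")
  for (f in c(counts_file, taxonomy_file, metadata_file)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }

  cnt <- utils::read.delim(counts_file, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(cnt)[1] != "sample_id") stop("counts.tsv must start with a sample_id column")
  if (anyDuplicated(cnt$sample_id)) stop("duplicate sample ids in counts table")
  mat <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(mat) <- cnt$sample_id
  if (anyDuplicated(colnames(mat))) stop("duplicate taxon ids in counts table")

  tax <- utils::read.delim(taxonomy_file, stringsAsFactors = FALSE)
  need <- c("taxon_id", "domain", "marker")
  missing_cols <- setdiff(need, names(tax))
  if (length(missing_cols)) {
    stop("taxonomy.tsv lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tax$taxon_id)) stop("duplicate taxon ids in taxonomy")
  unannotated <- setdiff(colnames(mat), tax$taxon_id)
  if (length(unannotated)) {
    stop("taxa without taxonomy annotation: ", paste(unannotated, collapse = ", "))
  }
  domain <- stats::setNames(tax$domain, tax$taxon_id)
  marker <- stats::setNames(tax$marker, tax$taxon_id)
  taxonomy <- if ("lineage" %in% names(tax)) stats::setNames(tax$lineage, tax$taxon_id)

  meta <- utils::read.delim(metadata_file, stringsAsFactors = FALSE)
  meta <- validate_metadata(meta)

  only_counts <- setdiff(rownames(mat), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, rownames(mat))
  if (length(only_counts) || length(only_meta)) {
    message("sample id mismatch: ", length(only_counts),
            " count-only, ", length(only_meta), " metadata-only sample(s)")
  }

  list(
    counts = count_table(mat, domain = domain, marker = marker, taxonomy = taxonomy),
    metadata = meta
  )
}

#' Write a count/taxonomy/metadata bundle as tab-separated files
#'
#' Inverse of [read_bundle()]; the round trip is the identity on counts and
#' annotations.
#'
#' @param counts A [count_table].
#' @param metadata A `sample_metadata` data frame (or `NULL` to skip).
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(counts, metadata = NULL, dir) {
  stopifnot(inherits(counts, "count_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cnt <- data.frame(sample_id = sample_ids(counts), counts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tax <- data.frame(taxon_id = taxon_ids(counts),
                    domain = unname(counts$domain),
                    marker = unname(counts$marker),
                    stringsAsFactors = FALSE)
  if (!is.null(counts$taxonomy)) tax$lineage <- unname(counts$taxonomy)
  utils::write.table(tax, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(metadata)) {
    utils::write.table(as.data.frame(metadata), file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write an interaction network to file
#'
#' Formats: `"graphml"` (full node/edge attributes), `"edgelist"`
#' (tab-separated `source`, `target`, `weight`, full double precision) and
#' `"json"` (nodes and edges with attributes, plus provenance).
#'
#' @param net An [interaction_network].
#' @param path Output file path.
#' @param format One of `"graphml"`, `"edgelist"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist", "json")) {
  format <- match.arg(format)
  g <- as_graph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    if (igraph::ecount(g) > 0) {
      ends <- igraph::ends(g, igraph::E(g))
      df <- data.frame(source = ends[, 1], target = ends[, 2],
                       weight = sprintf("%.17g", igraph::E(g)$weight),
                       stringsAsFactors = FALSE)
    } else {
      df <- data.frame(source = character(0), target = character(0),
                       weight = character(0))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nodes <- data.frame(id = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
                        domain = igraph::V(g)$domain %||% NA_character_,
                        marker = igraph::V(g)$marker %||% NA_character_,
                        stringsAsFactors = FALSE)
    edges <- if (igraph::ecount(g) > 0) {
      ends <- igraph::ends(g, igraph::E(g))
      data.frame(source = ends[, 1], target = ends[, 2],
                 weight = igraph::E(g)$weight,
                 stability = igraph::E(g)$stability %||% NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(source = character(0), target = character(0),
                 weight = numeric(0), stability = numeric(0))
    }
    payload <- list(nodes = nodes, edges = edges)
    if (inherits(net, "interaction_network") && !is.null(net$provenance)) {
      prov <- net$provenance
      prov$params <- NULL  # functions do not serialize; scalars live in the run log
      prov$instability <- NULL
      payload$provenance <- prov
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read an interaction network written by [write_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return An [interaction_network].
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "each")
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "numeric"))
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
    if (nrow(df) > 0) igraph::E(g)$weight <- df$weight
  }
  interaction_network(g)
}

#' Serialize a ground-truth model to JSON
#'
#' Stores the edge list, per-taxon domain/marker, the precision matrix and
#' the seed; [read_true_model()] restores an identical object.
#'
#' @param truth A `true_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_true_model <- function(truth, path) {
  stopifnot(inherits(truth, "true_model"))
  payload <- list(
    taxa = names(truth$domain_of),
    domain_of = as.list(truth$domain_of),
    marker_of = as.list(truth$marker_of),
    true_edges = as.data.frame(truth$true_edges, stringsAsFactors = FALSE),
    precision = truth$precision,
    seed = truth$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_true_model
#' @param path Path of a JSON file written by [write_true_model()].
#' @export
read_true_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  omega <- as.matrix(x$precision)
  dimnames(omega) <- list(x$taxa, x$taxa)
  edges <- as.matrix(x$true_edges)
  if (length(edges) == 0) edges <- matrix(character(0), 0, 2)
  colnames(edges) <- c("a", "b")
  structure(
    list(precision = omega,
         true_edges = edges,
         domain_of = unlist(x$domain_of)[x$taxa],
         marker_of = unlist(x$marker_of)[x$taxa],
         seed = x$seed),
    class = "true_model"
  )
}
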
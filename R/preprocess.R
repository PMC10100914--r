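#' Prevalence and abundance filtering of taxa
#'
#' Removes rare taxa before network inference: a taxon is retained only if it
#' is present (count > 0) in at least `min_prevalence` of the samples AND its
#' relative abundance reaches `min_mean_relabund`. Defaults follow the common
#' practice of discarding ASVs present in fewer than 30% of samples or below
#' a relative abundance of 1e-4, so that inference concentrates on widely
#' shared community members.
#'
#' @param counts A [count_table].
#' @param min_prevalence Minimum fraction of samples with a nonzero count.
#' @param min_mean_relabund Minimum relative abundance. How per-sample
#'   relative abundances are aggregated is set by `abundance_stat`.
#' @param abundance_stat `"mean"` (default; the stricter reading) or `"max"`
#'   across samples.
#' @return A filtered [count_table] with attribute `removed` (named integer:
#'   `by_prevalence`, `by_abundance`, `total`). Filtering is idempotent.
#' @export
filter_taxa <- function(counts, min_prevalence = 0.30, min_mean_relabund = 1e-4,
                        abundance_stat = c("mean", "max")) {
  stopifnot(inherits(counts, "count_table"))
  abundance_stat <- match.arg(abundance_stat)
  mat <- counts$counts
  if (nrow(mat) == 0 || ncol(mat) == 0) stop("count table is empty")

  prevalence <- colMeans(mat > 0)
  totals <- rowSums(mat)
  rel <- mat / ifelse(totals > 0, totals, 1)  # zero-depth samples contribute 0
  relstat <- if (abundance_stat == "mean") colMeans(rel) else apply(rel, 2, max)

  pass_prev <- prevalence >= min_prevalence
  pass_abund <- relstat >= min_mean_relabund
  keep <- pass_prev & pass_abund
  if (!any(keep)) {
    stop("all ", ncol(mat), " taxa removed by filtering (empty result)")
  }
  out <- keep_taxa(counts, colnames(mat)[keep])
  attr(out, "removed") <- c(
    by_prevalence = sum(!pass_prev),
    by_abundance = sum(!pass_abund),
    total = sum(!keep)
  )
  out
}

#' Centered log-ratio transform, per marker block
#'
#' Applies the CLR transform `x -> ln(x + pseudocount) - mean(ln(x + pseudocount))`
#' to each sample, separately within each marker-gene block (16S and 18S taxa
#' are closed compositions of different sequencing libraries, so they are
#' transformed jointly only within their own block and then concatenated).
#' Each sample's row sums to zero within every block.
#'
#' @param counts A [count_table].
#' @param pseudocount Positive value added before the log (default 1).
#' @return A [clr_matrix] with the same sample/taxon order as `counts`.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "count_table"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  mat <- counts$counts
  if (ncol(mat) == 0) stop("empty count table: no taxa to transform")
  out <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  markers <- intersect(c("16S", "18S"), unique(counts$marker))
  blocks <- lapply(markers, function(m) colnames(mat)[counts$marker == m])
  names(blocks) <- markers
  for (m in markers) {
    cols <- blocks[[m]]
    if (length(cols) == 0) stop("empty marker block: ", m)
    lg <- log(mat[, cols, drop = FALSE] + pseudocount)
    out[, cols] <- lg - rowMeans(lg)
  }
  clr_matrix(out, pseudocount = pseudocount, marker_blocks = blocks)
}

#' Subset a count table to selected domains
#'
#' Produces the taxon subsets behind the network variants: bacteria + archaea
#' + fungi (BAF), bacteria + archaea (BA), bacteria + fungi (BF),
#' bacteria-only (B) and fungi-only (F). Samples are unchanged.
#'
#' @param counts A [count_table].
#' @param domains Non-empty subset of `c("bacteria", "archaea", "fungus")`.
#' @return A [count_table] restricted to taxa of the requested domains.
#' @export
subset_domains <- function(counts, domains) {
  stopifnot(inherits(counts, "count_table"))
  allowed <- c("bacteria", "archaea", "fungus")
  if (length(domains) == 0) stop("domains must be non-empty")
  bad <- setdiff(domains, allowed)
  if (length(bad)) stop("unknown domain(s): ", paste(bad, collapse = ", "))
  keep <- taxon_ids(counts)[counts$domain %in% domains]
  if (length(keep) == 0) {
    stop("no taxa left after domain subsetting (", paste(domains, collapse = "+"), ")")
  }
  keep_taxa(counts, keep)
}

#' Discretize methane into a binary high/low response
#'
#' Labels each sample `"high"` or `"low"` in methane-related activity. Under
#' `mode = "by_depth"` a sample is `"high"` iff its depth interval overlaps
#' the sulfate-methane transition zone (SMTZ), the sediment horizon where
#' anaerobic methane oxidation peaks. Under `mode = "by_concentration"` a
#' sample is `"high"` iff its methane concentration exceeds the mean methane
#' of its site's surface layer (the shallowest depth slice).
#'
#' @param meta A `sample_metadata` data frame (see [validate_metadata()]).
#' @param smtz_interval_cm SMTZ depth interval, centimetres below sea floor.
#' @param mode `"by_depth"` (default) or `"by_concentration"`.
#' @return A factor (levels `low`, `high`) named by sample id, with attribute
#'   `provenance` recording the rule used.
#' @export
discretize_methane <- function(meta, smtz_interval_cm = c(10, 13),
                               mode = c("by_depth", "by_concentration")) {
  mode <- match.arg(mode)
  meta <- validate_metadata(as.data.frame(meta))
  if (mode == "by_depth") {
    high <- meta$depth_top_cm < smtz_interval_cm[2] &
      meta$depth_bottom_cm > smtz_interval_cm[1]
  } else {
    if (!"methane" %in% names(meta) || all(is.na(meta$methane))) {
      stop("mode 'by_concentration' requires methane measurements")
    }
    surface_mean <- vapply(split(meta, meta$site), function(d) {
      surf <- d[d$depth_top_cm == min(d$depth_top_cm), , drop = FALSE]
      mean(surf$methane, na.rm = TRUE)
    }, numeric(1))
    high <- meta$methane > surface_mean[meta$site]
  }
  labels <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  names(labels) <- meta$sample_id
  attr(labels, "provenance") <- list(mode = mode, smtz_interval_cm = smtz_interval_cm)
  labels
}
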
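#' Per-sample balance value of two taxon groups
#'
#' A balance is a normalized log-contrast between the geometric means of a
#' numerator group (size p) and a denominator group (size q):
#' `B = sqrt(pq/(p+q)) * (mean log x_num - mean log x_den)`, computed on
#' zero-replaced counts (`counts + pseudocount`). Swapping the groups negates
#' every value, and multiplying a sample's zero-replaced counts by a constant
#' leaves its balance unchanged.
#'
#' @param counts A [count_table] or numeric matrix (samples x taxa).
#' @param numerator_taxa,denominator_taxa Disjoint, non-empty taxon id sets
#'   present in the table.
#' @param pseudocount Positive zero replacement (default 1).
#' @return Named numeric vector of per-sample balance values.
#' @export
balance_value <- function(counts, numerator_taxa, denominator_taxa, pseudocount = 1) {
  mat <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  if (length(numerator_taxa) == 0 || length(denominator_taxa) == 0) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(numerator_taxa, denominator_taxa)) > 0) {
    stop("numerator and denominator groups overlap")
  }
  absent <- setdiff(c(numerator_taxa, denominator_taxa), colnames(mat))
  if (length(absent)) stop("taxa not in table: ", paste(absent, collapse = ", "))
  L <- log(mat + pseudocount)
  p <- length(numerator_taxa); q <- length(denominator_taxa)
  sqrt(p * q / (p + q)) *
    (rowMeans(L[, numerator_taxa, drop = FALSE]) -
       rowMeans(L[, denominator_taxa, drop = FALSE]))
}

# Rank-based AUC of score s for the positive class (ties by midranks).
.auc <- function(s, positive) {
  n1 <- sum(positive); n0 <- length(s) - n1
  (sum(rank(s)[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUC for every column of a score matrix.
.auc_cols <- function(M, positive) {
  n1 <- sum(positive); n0 <- nrow(M) - n1
  r <- apply(M, 2, rank)
  (colSums(r[positive, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Greedy balance selection with repeated cross-validation
#'
#' Searches for the two-group log-contrast (balance) of taxa that best
#' separates a binary response, and measures how reproducibly each taxon is
#' selected. Within the training portion of every repeat x fold split, the
#' procedure scores all taxon pairs by the AUC of their balance as a
#' univariate ranking classifier, then greedily adds one taxon at a time to
#' whichever side improves the training AUC most, stopping at `max_size`
#' taxa or when the improvement drops below `min_improve`. The taxa that end
#' on the side elevated in `"high"` samples are recorded; appearance
#' frequencies aggregate over all `n_repeats * n_folds` validation steps,
#' and the balance's AUC on the held-out fold is averaged into
#' `mean_cv_auc`.
#'
#' @param counts A [count_table] or numeric matrix (samples x taxa).
#' @param response Factor or character of `"high"`/`"low"` per sample, named
#'   by sample id or in row order.
#' @param n_folds Folds per repeat (stratified by class; default 5).
#' @param n_repeats Number of repeated fold splits (default 100; heavier
#'   screens use 2000 repeats for 10,000 validation steps).
#' @param max_size Maximum total number of taxa in the balance (default 8).
#' @param pseudocount Zero replacement before logs (default 1).
#' @param min_improve Minimum training-AUC gain to accept a greedy step.
#'   The default 0.02 is roughly half the standard error of an empirical AUC
#'   at the cohort sizes this screen targets (SE ~ 0.04 at 160 training
#'   samples); smaller gains are indistinguishable from ranking noise, and
#'   admitting them lets persistent chance correlates of the response ride
#'   into every balance.
#' @param seed Master seed; each repeat's fold split derives its own seed.
#' @return A `balance_cv_report`: `freq` (named per-taxon appearance
#'   frequency in the selected balance, either side), `freq_high` (appearance
#'   frequency on the side elevated in `"high"` samples, the quantity the
#'   signature screen thresholds), `mean_cv_auc`, `n_repeats`, `n_folds`,
#'   `last_balance` (numerator/denominator of the final training fit, for
#'   inspection), `seed`.
#' @export
greedy_balance_cv <- function(counts, response, n_folds = 5, n_repeats = 100,
                              max_size = 8, pseudocount = 1,
                              min_improve = 0.02, seed = 1) {
  mat <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  n <- nrow(mat); taxa <- colnames(mat); p_all <- length(taxa)
  if (p_all < 2) stop("need at least 2 taxa")

  response <- as.character(unname(
    if (!is.null(names(response)) && !is.null(rownames(mat))) response[rownames(mat)]
    else response))
  if (!all(response %in% c("high", "low"))) stop("response must be 'high'/'low'")
  y <- response == "high"
  n_high <- sum(y); n_low <- n - n_high
  if (n_high == 0 || n_low == 0) stop("both response classes must be present")
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_folds > min(n_high, n_low)) stop("n_folds exceeds the smaller class size")

  L <- log(mat + pseudocount)
  pair_idx <- which(upper.tri(matrix(0, p_all, p_all)), arr.ind = TRUE)

  appear <- stats::setNames(numeric(p_all), taxa)
  appear_high <- stats::setNames(numeric(p_all), taxa)
  auc_sum <- 0; n_steps <- 0L
  last_balance <- NULL

  with_seed(seed, {
    for (rep in seq_len(n_repeats)) {
      set.seed(derive_seed(seed, rep))
      fold <- integer(n)
      fold[y]  <- sample(rep_len(seq_len(n_folds), n_high))
      fold[!y] <- sample(rep_len(seq_len(n_folds), n_low))
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        fitted <- .greedy_balance_fit(L[tr, , drop = FALSE], y[tr], pair_idx,
                                      max_size, min_improve)
        # orientation: which side is elevated in "high" training samples
        b_tr <- fitted$score
        high_side <- if (mean(b_tr[y[tr]]) >= mean(b_tr[!y[tr]])) "num" else "den"
        winners <- if (high_side == "num") fitted$num else fitted$den
        appear[taxa[c(fitted$num, fitted$den)]] <-
          appear[taxa[c(fitted$num, fitted$den)]] + 1
        appear_high[taxa[winners]] <- appear_high[taxa[winners]] + 1

        b_te <- .balance_score(L[!tr, , drop = FALSE], fitted$num, fitted$den)
        if (high_side == "den") b_te <- -b_te
        auc_sum <- auc_sum + .auc(b_te, y[!tr])
        n_steps <- n_steps + 1L
        last_balance <- list(numerator_taxa = taxa[fitted$num],
                             denominator_taxa = taxa[fitted$den],
                             high_side = high_side)
      }
    }
  })

  structure(
    list(freq = appear / n_steps, freq_high = appear_high / n_steps,
         mean_cv_auc = auc_sum / n_steps,
         n_repeats = n_repeats, n_folds = n_folds,
         last_balance = last_balance, seed = seed),
    class = "balance_cv_report"
  )
}

.balance_score <- function(L, num, den) {
  p <- length(num); q <- length(den)
  sqrt(p * q / (p + q)) *
    (rowMeans(L[, num, drop = FALSE]) - rowMeans(L[, den, drop = FALSE]))
}

# Greedy forward search on a training log-abundance matrix. Works on column
# indices; AUC is invariant to the balance's positive scaling factor, so
# candidate scores drop it.
.greedy_balance_fit <- function(Lt, yt, pair_idx, max_size, min_improve) {
  # best single pair, both orientations covered by auc and 1 - auc
  D <- Lt[, pair_idx[, 2], drop = FALSE] - Lt[, pair_idx[, 1], drop = FALSE]
  auc_f <- .auc_cols(D, yt)
  flip <- auc_f < 0.5
  auc_pair <- ifelse(flip, 1 - auc_f, auc_f)
  best <- which.max(auc_pair)
  if (flip[best]) {
    num <- pair_idx[best, 1]; den <- pair_idx[best, 2]
  } else {
    num <- pair_idx[best, 2]; den <- pair_idx[best, 1]
  }
  current_auc <- auc_pair[best]

  p_all <- ncol(Lt)
  repeat {
    if (length(num) + length(den) >= max_size) break
    rest <- setdiff(seq_len(p_all), c(num, den))
    if (length(rest) == 0) break
    sum_num <- rowSums(Lt[, num, drop = FALSE])
    sum_den <- rowSums(Lt[, den, drop = FALSE])
    pn <- length(num); qd <- length(den)
    # candidate scores: taxon added to numerator, then to denominator
    cand_num <- (sum_num + Lt[, rest, drop = FALSE]) / (pn + 1) - sum_den / qd
    cand_den <- sum_num / pn - (sum_den + Lt[, rest, drop = FALSE]) / (qd + 1)
    aucs <- .auc_cols(cbind(cand_num, cand_den), yt)
    k <- which.max(aucs)
    if (aucs[k] - current_auc < min_improve) break
    if (k <= length(rest)) num <- c(num, rest[k])
    else den <- c(den, rest[k - length(rest)])
    current_auc <- aucs[k]
  }
  list(num = num, den = den, auc = current_auc,
       score = .balance_score(Lt, num, den))
}

#' @export
print.balance_cv_report <- function(x, ...) {
  cat(sprintf("balance_cv_report: %d repeats x %d folds (%d validation steps)\n",
              x$n_repeats, x$n_folds, x$n_repeats * x$n_folds))
  cat(sprintf("  mean held-out AUC = %.3f\n", x$mean_cv_auc))
  top <- sort(x$freq_high[x$freq_high > 0], decreasing = TRUE)
  if (length(top)) {
    cat("  top high-side taxa:",
        paste(sprintf("%s (%.2f)", names(top)[seq_len(min(5, length(top)))],
                      top[seq_len(min(5, length(top)))]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Signature taxa from a balance-selection report
#'
#' Taxa whose appearance frequency on the high-favoring side of the balance
#' reaches `threshold` (and is nonzero) across validation steps; with the
#' default 0.30 this is
#' the screen for "high-methane-signature" taxa.
#'
#' @param report A `balance_cv_report`.
#' @param threshold Minimum appearance frequency (default 0.30).
#' @return Character vector of taxon ids (possibly empty).
#' @export
signature_taxa <- function(report, threshold = 0.30) {
  stopifnot(inherits(report, "balance_cv_report"))
  names(report$freq_high)[report$freq_high >= threshold & report$freq_high > 0]
}
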
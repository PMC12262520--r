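#' Rescale bin counts to sorted cell proportions
#'
#' PCR amplification inflates counts from bins holding few cells. When a
#' FACS sort report is available, each bin's counts are rescaled so the
#' bin's share of reads within a replicate matches its share of sorted
#' cells: for variant v, replicate r, bin k,
#' \deqn{\tilde y_{vrk} = y_{vrk} \, \pi_{rk} R_r / R_{rk}}
#' where \eqn{\pi_{rk}} is the cell proportion, \eqn{R_{rk}} the replicate's
#' total reads in bin k and \eqn{R_r} its total reads across bins. After
#' rescaling, per replicate the bin read shares equal \eqn{\pi_{rk}}.
#'
#' When `report` is `NULL` the data are returned unchanged with a warning:
#' the model's replicate-specific baseline can still absorb this bias.
#'
#' @param data a [count_dataset()] of raw counts.
#' @param report a [sort_report()], or `NULL` to skip normalization.
#' @return a `count_dataset` of normalized (real-valued) counts.
#' @export
normalize_counts <- function(data, report) {
  if (is.null(report)) {
    warning("no sort report supplied; skipping cell-proportion normalization")
    return(data)
  }
  if (!inherits(report, "sort_report")) report <- sort_report(report)
  k <- n_bins(data)
  y <- count_matrix(data)
  out <- y
  for (r in unique(data$replicate)) {
    idx <- data$replicate == r
    R_rk <- colSums(y[idx, , drop = FALSE])
    R_r <- sum(R_rk)
    rep_rows <- report[report$replicate == r, ]
    for (kk in seq_len(k)) {
      pi_rk <- rep_rows$cell_proportion[rep_rows$bin == kk]
      if (length(pi_rk) != 1L) {
        stop("missing sort report entry for replicate '", r, "', bin ", kk)
      }
      if (R_rk[kk] == 0 && pi_rk > 0) {
        stop("cannot rescale: replicate '", r, "', bin ", kk,
             " has zero reads but positive cell proportion")
      }
      out[idx, kk] <- y[idx, kk] * pi_rk * R_r / R_rk[kk]
    }
  }
  res <- as.data.frame(data)
  res[, count_cols(k)] <- out
  count_dataset(res, k_bins = k)
}

#' Depth filter and pseudocount
#'
#' Removes variants whose summed raw counts across all replicates and bins
#' fall below `min_total` (default 15), then adds `pseudocount` (default
#' 0.5) to every remaining bin count. Filtering always precedes
#' pseudocounting, so pseudocounts can never rescue a sub-threshold variant.
#'
#' @param data a [count_dataset()].
#' @param min_total variants with total counts strictly below this are
#'   dropped in all replicates.
#' @param pseudocount added to every bin count of retained variants.
#' @return filtered, pseudocounted `count_dataset`.
#' @export
filter_and_pseudocount <- function(data, min_total = 15, pseudocount = 0.5) {
  if (nrow(data) == 0L) stop("empty count dataset")
  k <- n_bins(data)
  y <- count_matrix(data)
  totals <- tapply(rowSums(y), data$variant, sum)
  keep_variants <- names(totals)[totals >= min_total]
  keep <- data$variant %in% keep_variants
  if (!any(keep)) stop("all variants removed by the count filter")
  res <- as.data.frame(data)[keep, , drop = FALSE]
  if (!any(res$class == "synonymous") && any(data$class == "synonymous")) {
    stop("all synonymous variants removed by the count filter; ",
         "the model cannot be fit without negative controls")
  }
  res[, count_cols(k)] <- res[, count_cols(k)] + pseudocount
  rownames(res) <- NULL
  count_dataset(res, k_bins = k)
}
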
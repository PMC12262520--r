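#' Construct a count dataset
#'
#' A `count_dataset` is a data frame with one row per (variant, replicate)
#' and the columns `variant`, `position`, `mutation`, `class`, `replicate`,
#' followed by `K` count columns `c1..cK`, bins ordered low to high
#' fluorescence. Counts may be real-valued after sort-proportion
#' normalization or pseudocounting; raw counts are integers.
#'
#' @param df data frame with the columns above.
#' @param k_bins number of fluorescence bins `K` (>= 2).
#' @param validate check invariants (default `TRUE`).
#' @return a `count_dataset` (data frame subclass with attribute `k_bins`).
#' @export
count_dataset <- function(df, k_bins, validate = TRUE) {
  stopifnot(is.data.frame(df), length(k_bins) == 1L, k_bins >= 2)
  req <- c("variant", "position", "mutation", "class", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  cc <- count_cols(k_bins)
  miss <- setdiff(cc, names(df))
  if (length(miss) > 0L) {
    stop("expected ", k_bins, " count columns ", paste(cc, collapse = ","),
         "; missing: ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[, c(req, cc)]
  df$variant <- as.character(df$variant)
  df$position <- as.integer(df$position)
  df$mutation <- as.character(df$mutation)
  df$class <- as.character(df$class)
  df$replicate <- as.character(df$replicate)
  for (col in cc) df[[col]] <- as.numeric(df[[col]])
  attr(df, "k_bins") <- as.integer(k_bins)
  class(df) <- c("count_dataset", "data.frame")
  if (validate) validate_count_dataset(df)
  df
}

count_cols <- function(k) paste0("c", seq_len(k))

#' Number of bins of a count dataset
#' @param data a `count_dataset`.
#' @return integer `K`.
#' @export
n_bins <- function(data) {
  k <- attr(data, "k_bins")
  if (is.null(k)) stop("not a count_dataset: missing k_bins attribute")
  k
}

#' Count matrix of a count dataset
#' @param data a `count_dataset`.
#' @return numeric matrix, one row per (variant, replicate), `K` columns.
#' @export
count_matrix <- function(data) {
  as.matrix(as.data.frame(data)[, count_cols(n_bins(data))])
}

validate_count_dataset <- function(data) {
  y <- count_matrix(data)
  if (anyNA(y)) stop("validation error: NA counts")
  if (any(y < 0)) stop("validation error: negative count")
  if (anyNA(data$position)) stop("validation error: non-integer position")
  key <- paste(data$variant, data$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("validation error: duplicated (variant, replicate) pair")
  }
  if (!any(data$class == "synonymous")) {
    warning("no synonymous-class variants: model fitting and baseline ",
            "scoring require synonymous negative controls")
  }
  invisible(data)
}

#' Read a tab-separated count table
#'
#' Expects a header with columns `variant`, `position`, `mutation`, `class`,
#' `replicate` and `k_bins` count columns `c1..cK` (bin 1 = lowest
#' fluorescence). Row order is preserved.
#'
#' @param path path to a TSV file.
#' @param k_bins expected number of bins.
#' @return a [count_dataset()].
#' @export
read_counts <- function(path, k_bins) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  found <- grep("^c[0-9]+$", names(df), value = TRUE)
  if (length(found) != k_bins) {
    stop("validation error: found ", length(found),
         " count columns but k_bins = ", k_bins)
  }
  count_dataset(df, k_bins = k_bins)
}

#' Write a count dataset as TSV
#' @param data a `count_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(data, path) {
  write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct or read a FACS sort report
#'
#' A sort report gives, per replicate and bin, the proportion of sorted
#' cells that fell in that bin; proportions must be positive and sum to 1
#' within each replicate (tolerance 1e-6).
#'
#' @param df data frame with columns `replicate`, `bin`, `cell_proportion`.
#' @return validated `sort_report` data frame.
#' @export
sort_report <- function(df) {
  req <- c("replicate", "bin", "cell_proportion")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("missing sort report column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[, req]
  df$replicate <- as.character(df$replicate)
  df$bin <- as.integer(df$bin)
  df$cell_proportion <- as.numeric(df$cell_proportion)
  if (any(df$cell_proportion <= 0)) {
    stop("validation error: cell proportions must be positive")
  }
  sums <- tapply(df$cell_proportion, df$replicate, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    bad <- names(sums)[abs(sums - 1) > 1e-6]
    stop("validation error: cell proportions do not sum to 1 in replicate(s) ",
         paste(bad, collapse = ", "))
  }
  class(df) <- c("sort_report", "data.frame")
  df
}

#' @rdname sort_report
#' @param path TSV file with columns `replicate`, `bin`, `cell_proportion`.
#' @export
read_sort_report <- function(path) {
  sort_report(read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE))
}
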
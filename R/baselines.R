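#' FACS gate thresholds
#'
#' Fluorescence bounds of the K sorting gates: contiguous, increasing, with
#' `upper[k] == lower[k+1]`. The outermost bounds default to 0 and `Inf` on
#' the fluorescence scale (the sort covers both tails).
#'
#' @param lower,upper length-K numeric vectors of gate bounds.
#' @return a `gate_thresholds` data frame with columns `bin`, `lower`,
#'   `upper`.
#' @export
gate_thresholds <- function(lower, upper) {
  stopifnot(length(lower) == length(upper), length(lower) >= 2)
  k <- length(lower)
  if (any(upper <= lower)) stop("each gate needs upper > lower")
  if (any(abs(upper[-k] - lower[-1]) > 1e-9 * pmax(1, abs(upper[-k])))) {
    stop("gates must be contiguous: upper[k] == lower[k+1]")
  }
  if (any(lower < 0)) stop("fluorescence bounds must be nonnegative")
  out <- data.frame(bin = seq_len(k), lower = lower, upper = upper)
  class(out) <- c("gate_thresholds", "data.frame")
  out
}

#' @rdname gate_thresholds
#' @param interior length-(K-1) increasing vector of interior gate
#'   boundaries; outer bounds are set to 0 and `Inf`.
#' @export
gates_from_interior <- function(interior) {
  stopifnot(length(interior) >= 1, all(interior > 0), !is.unsorted(interior,
            strictly = TRUE))
  gate_thresholds(c(0, interior), c(interior, Inf))
}

#' Weighted mean-bin scores
#'
#' The classical scorer: each (variant, replicate) gets the count-weighted
#' average bin index scaled to (0, 1],
#' `w_vr = sum_k (k/K) y_vrk / sum_k y_vrk`, variant scores are replicate
#' means, and the reported score is centered on the synonymous mean score.
#' Replicates with zero total count are omitted from the mean with a
#' warning.
#'
#' @param data a [count_dataset()] (raw or normalized counts; the score is
#'   scale-invariant per replicate).
#' @return a `baseline_scores` data frame: `variant`, `position`,
#'   `mutation`, `class`, `score`, `method = "meanbin"`.
#' @export
mean_bin_scores <- function(data) {
  K <- n_bins(data)
  y <- count_matrix(data)
  tot <- rowSums(y)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " replicate row(s) with zero total count omitted")
  }
  w <- as.numeric(y %*% (seq_len(K) / K)) / tot
  w[tot == 0] <- NA_real_
  mu <- tapply(w, data$variant, mean, na.rm = TRUE)
  if (any(is.nan(mu))) {
    stop("variant(s) with no positive-count replicate: ",
         paste(utils::head(names(mu)[is.nan(mu)], 5), collapse = ", "))
  }
  vinfo <- unique(as.data.frame(data)[, c("variant", "position", "mutation",
                                          "class")])
  rownames(vinfo) <- NULL
  mu_v <- as.numeric(mu[vinfo$variant])
  mu_syn <- mean(mu_v[vinfo$class == "synonymous"])
  if (is.nan(mu_syn)) stop("no synonymous variants to center the scores on")
  out <- data.frame(vinfo, score = mu_v - mu_syn, method = "meanbin")
  class(out) <- c("baseline_scores", "data.frame")
  out
}

# Negative log-likelihood of binned counts under LogNormal(mu, sigma):
# -sum_k y_k * log( F(U_k) - F(L_k) )
binned_lognormal_nll <- function(par, y, lo, hi) {
  mu <- par[1]
  sigma <- exp(par[2])
  pr <- stats::plnorm(hi, mu, sigma) - stats::plnorm(lo, mu, sigma)
  pr <- pmax(pr, 1e-300)
  -sum(y * log(pr))
}

#' Maximum-likelihood log-normal fit to binned counts
#'
#' Fits LogNormal(mu, sigma) to a length-K vector of bin counts given the
#' gate thresholds, by minimizing the binned negative log-likelihood with
#' Nelder-Mead over (mu, log sigma) from several starts.
#'
#' @param y length-K nonnegative counts (summed over replicates is fine:
#'   the likelihood is additive).
#' @param gates a [gate_thresholds()].
#' @return list with `mu`, `sigma`, `nll`, `converged`.
#' @export
fit_lognormal_bins <- function(y, gates) {
  K <- nrow(gates)
  stopifnot(length(y) == K)
  if (sum(y) <= 0) return(list(mu = NA_real_, sigma = NA_real_,
                               nll = NA_real_, converged = FALSE))
  # unidentifiable: all mass in a single tail-unbounded bin
  nz <- which(y > 0)
  if (length(nz) == 1L &&
      ((nz == 1L && gates$lower[1] == 0) ||
       (nz == K && is.infinite(gates$upper[K])))) {
    return(list(mu = NA_real_, sigma = NA_real_, nll = NA_real_,
                converged = FALSE))
  }
  # start from mean-bin-implied log-fluorescence quantiles
  lw <- log(pmax(gates$lower, 1e-12))
  up <- log(gates$upper)
  widths <- (up - lw)[is.finite(lw) & is.finite(up)]
  w0 <- if (length(widths) > 0) mean(widths) else 1
  zmid <- (lw + up) / 2
  if (!is.finite(zmid[1])) zmid[1] <- up[1] - w0 / 2
  if (!is.finite(zmid[K])) zmid[K] <- lw[K] + w0 / 2
  p <- y / sum(y)
  mu0 <- sum(p * zmid)
  best <- NULL
  for (s0 in c(0.25, 0.5, 1)) {
    fit <- tryCatch(
      optim(c(mu0, log(s0)), binned_lognormal_nll, y = y,
            lo = gates$lower, hi = gates$upper,
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(list(mu = NA_real_, sigma = NA_real_, nll = NA_real_,
                converged = FALSE))
  }
  list(mu = best$par[1], sigma = exp(best$par[2]), nll = best$value,
       converged = best$convergence == 0)
}

#' Maximum-likelihood log-normal scores
#'
#' Estimates each variant's latent fluorescence distribution as a
#' log-normal from its bin counts and the raw FACS gate thresholds, then
#' scores the variant as the difference between its location parameter and
#' the synonymous mean location. Counts are summed over replicates (the
#' binned likelihood is additive over observations). Variants whose fit
#' fails or is unidentifiable get `NA` scores and are flagged.
#'
#' @param data a [count_dataset()] of raw counts.
#' @param gates a [gate_thresholds()].
#' @return a `baseline_scores` data frame with columns `score`, `mu`,
#'   `sigma`, `converged`, `method = "ml"`.
#' @export
ml_lognormal_scores <- function(data, gates) {
  stopifnot(inherits(gates, "gate_thresholds"), nrow(gates) == n_bins(data))
  y <- count_matrix(data)
  ytot <- rowsum(y, data$variant)
  vinfo <- unique(as.data.frame(data)[, c("variant", "position", "mutation",
                                          "class")])
  rownames(vinfo) <- NULL
  fits <- lapply(vinfo$variant, function(v)
    fit_lognormal_bins(ytot[v, ], gates))
  mu <- vapply(fits, `[[`, numeric(1), "mu")
  sigma <- vapply(fits, `[[`, numeric(1), "sigma")
  converged <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!converged)) {
    warning(sum(!converged), " variant(s) flagged: log-normal fit failed ",
            "or location unidentifiable")
  }
  mu_syn <- mean(mu[vinfo$class == "synonymous"], na.rm = TRUE)
  out <- data.frame(vinfo, score = mu - mu_syn, mu = mu, sigma = sigma,
                    converged = converged, method = "ml")
  class(out) <- c("baseline_scores", "data.frame")
  out
}

#' Discovery calling from the synonymous score distribution
#'
#' Fits a normal null to the synonymous scores and assigns each variant a
#' two-sided p-value under it; discoveries are called at `p < alpha`
#' (default 0.05, approximately a 2-standard-deviation cutoff). No multiple
#' testing correction is applied, matching how fixed-SD cutoffs are used in
#' practice.
#'
#' @param scores a `baseline_scores` data frame (from [mean_bin_scores()]
#'   or [ml_lognormal_scores()]).
#' @param syn_labels logical vector marking synonymous rows; defaults to
#'   `scores$class == "synonymous"`.
#' @param alpha discovery threshold on the p-value.
#' @param robust use median/MAD instead of mean/SD for the null fit.
#' @return `scores` with added `p_value`, `discovery`, `sign` columns;
#'   null parameters attached as attributes `null_mean`, `null_sd`.
#' @export
synonymous_null_threshold <- function(scores, syn_labels = NULL,
                                      alpha = 0.05, robust = FALSE) {
  if (is.null(syn_labels)) syn_labels <- scores$class == "synonymous"
  stopifnot(length(syn_labels) == nrow(scores))
  syn_scores <- scores$score[syn_labels & !is.na(scores$score)]
  if (length(syn_scores) < 3L) {
    stop("need at least 3 synonymous scores to fit the null")
  }
  mu0 <- if (robust) median(syn_scores) else mean(syn_scores)
  sd0 <- if (robust) mad(syn_scores) else sd(syn_scores)
  if (!is.finite(sd0) || sd0 <= 0) stop("degenerate synonymous null (sd = 0)")
  z <- (scores$score - mu0) / sd0
  scores$p_value <- 2 * pnorm(-abs(z))
  scores$discovery <- !is.na(scores$p_value) & scores$p_value < alpha
  scores$sign <- ifelse(!scores$discovery, "none",
                        ifelse(scores$score > mu0, "GOF", "LOF"))
  attr(scores, "null_mean") <- mu0
  attr(scores, "null_sd") <- sd0
  scores
}
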
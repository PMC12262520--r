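#' Standard-normal quantile cutoffs of a bin-probability simplex
#'
#' Maps baseline bin probabilities `q` (length K, positive, summing to 1)
#' to the K-1 interior cutoffs `t_k = qnorm(q_1 + ... + q_k)` of a standard
#' normal whose bin masses reproduce `q`.
#'
#' @param q length-K probability vector, all entries > 0.
#' @return strictly increasing numeric vector of length K-1.
#' @export
quantile_cutoffs <- function(q) {
  if (any(q <= 0)) stop("all bin probabilities must be positive")
  if (abs(sum(q) - 1) > 1e-8) stop("bin probabilities must sum to 1")
  k <- length(q)
  if (k < 2L) stop("need at least 2 bins")
  t <- qnorm(cumsum(q)[seq_len(k - 1L)])
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop("degenerate cutoffs (a bin probability is numerically zero)")
  }
  t
}

#' Bin probabilities of a shifted latent normal
#'
#' Given cutoffs `t` (from [quantile_cutoffs()]) and an effect size `beta`
#' in standard-normal quantile units, returns the bin masses of a
#' Normal(beta, 1) latent fluorescence against those cutoffs:
#' `p_k = pnorm(t_k - beta) - pnorm(t_{k-1} - beta)` with `t_0 = -Inf`,
#' `t_K = Inf`. At `beta = 0` this inverts [quantile_cutoffs()] and returns
#' the baseline `q`. Positive `beta` moves mass to higher bins.
#'
#' @param t strictly increasing cutoff vector, length K-1.
#' @param beta effect size (scalar).
#' @return length-K probability vector summing to 1.
#' @export
shifted_bin_probabilities <- function(t, beta) {
  if (length(t) >= 2L && any(diff(t) <= 0)) {
    stop("cutoffs must be strictly increasing")
  }
  stopifnot(length(beta) == 1L, is.finite(beta))
  diff(pnorm(c(-Inf, t, Inf) - beta))
}

#' Dirichlet-multinomial log density with real-valued counts
#'
#' Log density of counts `y` under a Dirichlet-multinomial with total `N`
#' and concentration `phi * p`. Factorials are evaluated through `lgamma`,
#' so real-valued counts (sort-normalized, pseudocounted) are accepted; for
#' integer counts this equals the standard DM pmf, including the
#' multinomial coefficient.
#'
#' @param counts length-K nonnegative vector.
#' @param N total count, `sum(counts)`.
#' @param phi overdispersion concentration, > 0 (larger = closer to
#'   multinomial).
#' @param p length-K probability vector.
#' @return log density (scalar).
#' @export
dm_log_density <- function(counts, N = sum(counts), phi, p) {
  if (length(phi) != 1L || !is.finite(phi) || phi <= 0) {
    stop("domain error: phi must be a positive scalar")
  }
  if (length(p) != length(counts)) stop("length mismatch between counts and p")
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-6) {
    stop("domain error: p must be a positive probability vector")
  }
  if (any(counts < 0)) stop("domain error: negative counts")
  if (abs(sum(counts) - N) > 1e-6 * max(1, N)) {
    stop("N does not match sum(counts)")
  }
  a <- phi * p
  lgamma(N + 1) - sum(lgamma(counts + 1)) +
    lgamma(phi) - lgamma(N + phi) +
    sum(lgamma(counts + a) - lgamma(a))
}

#' Linear count-overdispersion trend
#'
#' The model's per-replicate overdispersion is a linear function of the
#' variant's (normalized) total count: `phi = a + b * N`.
#'
#' @param a intercept, >= 0.
#' @param b slope, >= 0.
#' @param N total count, >= 0.
#' @return overdispersion `phi` (> 0).
#' @export
overdispersion_trend <- function(a, b, N) {
  if (a < 0 || b < 0) stop("domain error: a and b must be nonnegative")
  phi <- a + b * N
  if (any(phi <= 0)) stop("domain error: nonpositive overdispersion")
  phi
}
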
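# Hierarchical Bayesian model for sort-seq bin counts.
#
# Likelihood (per variant v, replicate r over K bins):
#   y_vr ~ DirichletMultinomial(N_vr, phi_vr * p_vr)
#   phi_vr = a_r + b_r * N_vr                   (overdispersion trend)
#   p_vrk  = Phi(t_rk - beta_v) - Phi(t_r,k-1 - beta_v)
#   t_rk   = qnorm(q_r1 + ... + q_rk)           (baseline cutoffs)
# Effects:
#   missense:   beta_v ~ N(theta_p, sigma_p^2)  (position hierarchy)
#               or beta_v ~ N(0, sigma_b^2)     (hierarchy off)
#   synonymous: beta_s ~ N(theta_s, sigma_0^2)  (fixed effect per mutation)
# Priors: theta_* ~ N(0,1); sigma_p, sigma_0, sigma_b ~ InvGamma(1,1);
# q_r ~ Dirichlet(1,...,1); a_r, b_r flat on [0, 500] / [0, 10].
#
# The Dirichlet-multinomial with real-valued (normalized, pseudocounted)
# counts is not a JAGS built-in; its log density kernel is encoded with the
# zeros trick: zeros[i] ~ dpois(C - loglik[i]) with observed zeros and a
# constant C large enough that the rate stays positive.

build_jags_model <- function(K, use_position_hierarchy) {
  mid_bins <- if (K > 2)
    "    for (k in 2:(K-1)) {
      pp[i,k] <- phi(t[rr[i],k] - beta[vv[i]]) - phi(t[rr[i],k-1] - beta[vv[i]])
    }\n" else ""
  effect_block <- if (use_position_hierarchy) "
  for (p in 1:P) {
    theta[p] ~ dnorm(0, 1)
    gp[p] ~ dgamma(1, 1)
    sigp[p] <- 1 / gp[p]
    taup[p] <- gp[p] * gp[p]
  }
  for (j in 1:nmis) {
    beta[mis[j]] ~ dnorm(theta[pos[j]], taup[pos[j]])
  }
" else "
  gb ~ dgamma(1, 1)
  sigb <- 1 / gb
  taub <- gb * gb
  for (j in 1:nmis) {
    beta[mis[j]] ~ dnorm(0, taub)
  }
"
  paste0("model {
  for (r in 1:R) {
    q[r,1:K] ~ ddirch(ones[1:K])
    for (k in 1:(K-1)) { t[r,k] <- probit(sum(q[r,1:k])) }
    a[r] ~ dunif(0, 500)
    b[r] ~ dunif(0, 10)
  }
", effect_block, "
  for (s in 1:S) {
    theta_s[s] ~ dnorm(0, 1)
    beta[synv[s]] ~ dnorm(theta_s[s], tau0)
  }
  g0 ~ dgamma(1, 1)
  sig0 <- 1 / g0
  tau0 <- g0 * g0
  for (i in 1:n) {
    phiv[i] <- a[rr[i]] + b[rr[i]] * N[i] + 1.0E-6
    pp[i,1] <- phi(t[rr[i],1] - beta[vv[i]])
", mid_bins, "    pp[i,K] <- 1 - phi(t[rr[i],K-1] - beta[vv[i]])
    ll[i] <- loggam(phiv[i]) - loggam(N[i] + phiv[i])
             + sum(loggam(Y[i,1:K] + phiv[i] * pp[i,1:K] + 1.0E-10)
                   - loggam(phiv[i] * pp[i,1:K] + 1.0E-10))
    zeros[i] ~ dpois(10000 - ll[i])
  }
}
")
}

#' Fit the hierarchical effect-size model
#'
#' Fits the Dirichlet-multinomial quantile-shift model by MCMC and returns
#' posterior draws of every latent quantity. The data should already be
#' normalized (if a sort report is available) and pseudocounted; see
#' [filter_and_pseudocount()].
#'
#' @param data a [count_dataset()] with at least 2 synonymous variants.
#' @param use_position_hierarchy if `TRUE` (default) missense effects are
#'   drawn from a per-position Normal(theta_p, sigma_p^2); if `FALSE`, from
#'   a shared Normal(0, sigma_b^2).
#' @param chains,warmup,samples MCMC settings: number of chains, warmup
#'   (including adaptation) and retained draws per chain.
#' @param seed integer seed; the same seed reproduces the draws exactly.
#' @param quiet suppress sampler progress output.
#' @return a `posterior_draws` object: matrices of draws (rows = draws
#'   across chains) for `beta`, baseline simplexes `q`, trend `a`, `b`,
#'   hierarchy parameters, plus variant metadata and convergence
#'   diagnostics (split into `$diagnostics`: R-hat and effective sample
#'   sizes; the slice/Gibbs sampler has no divergence count).
#' @seealso [bias_correct()], [lfsr_and_discoveries()], [score_variants()]
#' @export
fit_effects <- function(data, use_position_hierarchy = TRUE, chains = 4,
                        warmup = 1000, samples = 1000, seed = 1,
                        quiet = TRUE) {
  stopifnot(chains >= 1, warmup >= 2, samples >= 1)
  K <- n_bins(data)
  vinfo <- unique(as.data.frame(data)[, c("variant", "position", "mutation",
                                          "class")])
  rownames(vinfo) <- NULL
  V <- nrow(vinfo)
  syn <- vinfo$class == "synonymous"
  S <- sum(syn)
  if (S < 2L) {
    stop("need at least 2 synonymous variants to anchor the baseline and ",
         "bias-correct the scores; scoring against a known wild-type ",
         "baseline proportion instead is not supported")
  }
  reps <- sort(unique(data$replicate))
  R <- length(reps)
  y <- count_matrix(data)
  if (any(rowSums(y) <= 0)) stop("rows with zero total count; filter first")
  vv <- match(data$variant, vinfo$variant)
  rr <- match(data$replicate, reps)
  N <- rowSums(y)

  mis <- which(!syn)
  posm <- integer(0)
  pos_levels <- character(0)
  if (use_position_hierarchy && length(mis) > 0L) {
    pos_levels <- sort(unique(vinfo$position[mis]))
    posm <- match(vinfo$position[mis], pos_levels)
  }

  jdata <- list(R = R, K = K, S = S, n = nrow(y), nmis = length(mis),
                ones = rep(1, K), synv = which(syn),
                vv = vv, rr = rr, Y = y, N = N, zeros = rep(0, nrow(y)))
  if (length(mis) > 0L) {
    jdata$mis <- mis
    if (use_position_hierarchy) {
      jdata$P <- length(pos_levels)
      jdata$pos <- posm
    }
  } else {
    jdata$mis <- integer(0)
  }

  # baseline init from pooled synonymous proportions per replicate
  q_init <- t(vapply(reps, function(r) {
    cs <- colSums(y[data$replicate == r & syn[vv], , drop = FALSE]) + 0.5
    cs / sum(cs)
  }, numeric(K)))
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(beta = rep(0, V), theta_s = rep(0, S), g0 = 1,
                q = q_init, a = rep(1, R), b = rep(0.05, R),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (abs(seed) %% 1000000L) * 1000L + ch)
    if (use_position_hierarchy && length(mis) > 0L) {
      ini$theta <- rep(0, length(pos_levels))
      ini$gp <- rep(1, length(pos_levels))
    } else if (length(mis) > 0L) {
      ini$gb <- 1
    }
    ini
  })

  model_str <- build_jags_model(K, use_position_hierarchy &&
                                  length(mis) > 0L)
  monitors <- c("beta", "q", "a", "b", "sig0", "theta_s")
  if (use_position_hierarchy && length(mis) > 0L) {
    monitors <- c(monitors, "theta", "sigp")
  } else if (length(mis) > 0L) {
    monitors <- c(monitors, "sigb")
  }

  n_adapt <- max(100L, min(as.integer(warmup) %/% 2L, 1000L))
  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(model_str), data = jdata, inits = inits,
                      n.chains = chains, n.adapt = n_adapt, quiet = quiet),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  burn <- max(0L, as.integer(warmup) - n_adapt)
  if (burn > 0L) update(jm, burn, progress.bar = if (quiet) "none" else "text")
  sims <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = samples,
                              progress.bar = if (quiet) "none" else "text")

  diag <- mcmc_diagnostics(sims)
  mat <- as.matrix(do.call(rbind, lapply(sims, as.matrix)))
  pull <- function(prefix, n1, n2 = NULL) {
    if (is.null(n2)) {
      cols <- if (n1 == 1L && prefix %in% colnames(mat)) prefix
              else paste0(prefix, "[", seq_len(n1), "]")
    } else {
      cols <- as.vector(outer(seq_len(n1), seq_len(n2), function(i, j)
        paste0(prefix, "[", i, ",", j, "]")))
    }
    mat[, cols, drop = FALSE]
  }
  beta <- pull("beta", V)
  colnames(beta) <- vinfo$variant
  q_draws <- pull("q", R, K)
  out <- list(beta = beta, q = q_draws,
              a = pull("a", R), b = pull("b", R),
              sigma_0 = as.numeric(pull("sig0", 1)),
              theta_s = pull("theta_s", S),
              variants = vinfo, syn_idx = which(syn),
              replicates = reps, k_bins = K,
              use_position_hierarchy = use_position_hierarchy,
              n_draws = nrow(beta), seed = seed, diagnostics = diag)
  if (use_position_hierarchy && length(mis) > 0L) {
    out$theta_p <- pull("theta", length(pos_levels))
    out$sigma_p <- pull("sigp", length(pos_levels))
    out$positions <- pos_levels
  } else if (length(mis) > 0L) {
    out$sigma_beta <- as.numeric(pull("sigb", 1))
  }
  class(out) <- "posterior_draws"
  out
}

mcmc_diagnostics <- function(sims) {
  ess <- tryCatch(coda::effectiveSize(sims), error = function(e) NULL)
  rhat <- NULL
  if (length(sims) >= 2L) {
    rhat <- tryCatch({
      gd <- coda::gelman.diag(sims, multivariate = FALSE, autoburnin = FALSE)
      gd$psrf[, 1]
    }, error = function(e) NULL)
  }
  list(rhat_max = if (is.null(rhat)) NA_real_ else max(rhat, na.rm = TRUE),
       rhat = rhat,
       ess_min = if (is.null(ess)) NA_real_ else min(ess),
       divergences = NA_integer_)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", ncol(x$beta), "variants,",
      length(x$replicates), "replicates,", x$k_bins, "bins,",
      x$n_draws, "draws",
      if (x$use_position_hierarchy) "(position hierarchy)" else "", "\n")
  cat("  synonymous controls:", length(x$syn_idx), "\n")
  if (!is.na(x$diagnostics$rhat_max)) {
    cat("  max R-hat:", round(x$diagnostics$rhat_max, 3), "\n")
  }
  invisible(x)
}

#' Recalibrate posterior effect draws against synonymous controls
#'
#' For every variant v and retained draw d, subtracts the same-draw effect
#' of a randomly chosen synonymous variant:
#' `beta*_vd = beta_vd - beta_{s_vd, d}`, with `s_vd` uniform over the
#' synonymous set, sampled independently (with replacement) per (v, d).
#' This propagates negative-control variance into the score's posterior and
#' removes any shared offset between effects and baseline.
#'
#' @param draws a `posterior_draws` from [fit_effects()].
#' @param seed integer seed for the synonymous resampling.
#' @return a `corrected_draws` matrix (draws x variants) with the variant
#'   table attached as attribute `variants`.
#' @export
bias_correct <- function(draws, seed = 1) {
  stopifnot(inherits(draws, "posterior_draws"))
  syn_idx <- draws$syn_idx
  if (length(syn_idx) < 1L) stop("no synonymous variants in the fit")
  beta <- draws$beta
  D <- nrow(beta)
  V <- ncol(beta)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pick <- matrix(syn_idx[sample.int(length(syn_idx), D * V, replace = TRUE)],
                 nrow = D, ncol = V)
  baseline <- matrix(beta[cbind(rep(seq_len(D), V), as.vector(pick))],
                     nrow = D, ncol = V)
  corrected <- beta - baseline
  attr(corrected, "variants") <- draws$variants
  class(corrected) <- c("corrected_draws", class(corrected))
  corrected
}

#' Effect table: lfsr and discovery calls from corrected draws
#'
#' The local false sign rate of variant v is
#' `lfsr_v = min(mean(beta*_v <= 0), mean(beta*_v >= 0))` over corrected
#' posterior draws (draws exactly at 0 count on both sides; values are
#' capped at 0.5). A variant is a discovery when `lfsr < threshold`; its
#' sign is `GOF` for positive and `LOF` for negative posterior mean.
#'
#' @param corrected a `corrected_draws` matrix from [bias_correct()] (any
#'   draws x variants matrix works if it has a `variants` attribute).
#' @param threshold discovery threshold on lfsr (default 0.05).
#' @return an `effect_table` data frame: `variant`, `position`, `mutation`,
#'   `class`, `beta_hat`, `sigma_hat`, `lfsr`, `discovery`, `sign`.
#' @export
lfsr_and_discoveries <- function(corrected, threshold = 0.05) {
  if (is.null(dim(corrected)) || nrow(corrected) < 1L) {
    stop("empty draw matrix")
  }
  if (nrow(corrected) < 100L) {
    warning("fewer than 100 draws; lfsr estimates will be coarse")
  }
  vinfo <- attr(corrected, "variants")
  if (is.null(vinfo)) {
    vinfo <- data.frame(variant = colnames(corrected) %||%
                          paste0("v", seq_len(ncol(corrected))),
                        position = NA_integer_, mutation = NA_character_,
                        class = NA_character_)
  }
  m <- unclass(corrected)
  beta_hat <- colMeans(m)
  sigma_hat <- apply(m, 2, sd)
  lfsr <- pmin(colMeans(m <= 0), colMeans(m >= 0), 0.5)
  discovery <- lfsr < threshold
  sign <- ifelse(!discovery, "none", ifelse(beta_hat > 0, "GOF", "LOF"))
  out <- data.frame(vinfo, beta_hat = beta_hat, sigma_hat = sigma_hat,
                    lfsr = lfsr, discovery = discovery, sign = sign,
                    row.names = NULL)
  class(out) <- c("effect_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call scoring pipeline
#'
#' Convenience wrapper: [fit_effects()] then [bias_correct()] then
#' [lfsr_and_discoveries()].
#'
#' @inheritParams fit_effects
#' @param lfsr_threshold discovery threshold.
#' @param ... passed to [fit_effects()].
#' @return an `effect_table`; the fit is attached as attribute `draws`.
#' @export
score_variants <- function(data, seed = 1, lfsr_threshold = 0.05, ...) {
  draws <- fit_effects(data, seed = seed, ...)
  corrected <- bias_correct(draws, seed = seed + 1L)
  tab <- lfsr_and_discoveries(corrected, threshold = lfsr_threshold)
  attr(tab, "draws") <- draws
  tab
}
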
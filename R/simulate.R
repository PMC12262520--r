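# Generative model of a FACS sort-seq DMS experiment. The chain is:
#   effect pattern W  ->  ground-truth effects beta  ->  latent cell
#   fluorescence and sorted-cell bin probabilities  ->  observed reads
#   (variant-level Dirichlet-multinomial, or bin-level overdispersion).
# Parameters can be set directly (synthetic mode) or estimated from a seed
# count dataset (config_from_data), mirroring how a real experiment would
# be summarized.

#' Simulation configuration
#'
#' All generative parameters of the sort-seq simulator. Defaults describe a
#' fully synthetic mid-size screen; [config_from_data()] replaces them with
#' estimates from a seed dataset.
#'
#' @param P number of residue positions.
#' @param variants_per_position total variant slots per position (the first
#'   `syn_per_position` of them are synonymous controls with effect 0).
#' @param syn_per_position synonymous slots per position.
#' @param R replicates.
#' @param K fluorescence bins (bin 1 = lowest).
#' @param L total sequenced reads for the experiment.
#' @param m sorted cells per variant (default 200).
#' @param mixture effect-size mixture: list with `p_small`, `mu_small`,
#'   `sigma_small`, `mu_large`, `sigma_large` (log-fluorescence scale).
#' @param sigma_p SD of effects around their position mean.
#' @param effect_proportion target fraction of all variant slots carrying a
#'   nonzero effect (synonymous slots never do); ignored when `W` is given.
#' @param W optional P x `variants_per_position` binary effect pattern.
#' @param mu0,tau wild-type log-normal fluorescence location and scale.
#' @param B replicate-effect amplitude: replicate r gets a location shift
#'   `b_r`, the R equidistant steps in `[-B, B]`.
#' @param gate_offset shift of interior gate thresholds on the log scale.
#' @param eta_intercept,eta_slope variant overdispersion trend
#'   `eta = intercept + slope * mean read count` used when sampling reads.
#' @param psi optional length-K bin overdispersion; when set, reads are
#'   drawn per bin from the sorted cell pool instead of per variant.
#' @param read_pool optional vector of per-(variant, replicate) read totals
#'   to resample; when `NULL`, totals are drawn from a negative binomial
#'   with mean `L / (n_variants * R)` and size 10.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(P = 100, variants_per_position = 6,
                              syn_per_position = 1, R = 3, K = 4, L = 1e6,
                              m = 200,
                              mixture = list(p_small = 0.7, mu_small = 0,
                                             sigma_small = 0.15,
                                             mu_large = -1.5,
                                             sigma_large = 0.5),
                              sigma_p = 0.3, effect_proportion = 0.5,
                              W = NULL, mu0 = 5, tau = 0.5, B = 0,
                              gate_offset = 0, eta_intercept = 1,
                              eta_slope = 0.02, psi = NULL,
                              read_pool = NULL) {
  stopifnot(P >= 1, variants_per_position >= 1,
            syn_per_position >= 0,
            syn_per_position < variants_per_position,
            R >= 1, K >= 2, m >= 1, sigma_p >= 0, tau > 0,
            mixture$p_small >= 0, mixture$p_small <= 1,
            mixture$sigma_small > 0, mixture$sigma_large > 0)
  if (!is.null(W)) {
    stopifnot(is.matrix(W), nrow(W) == P,
              ncol(W) == variants_per_position, all(W %in% c(0, 1)))
  }
  if (!is.null(psi)) stopifnot(length(psi) == K, all(psi > 0))
  cfg <- list(P = P, V = variants_per_position, S = syn_per_position,
              R = R, K = K, L = L, m = m, mixture = mixture,
              sigma_p = sigma_p, effect_proportion = effect_proportion,
              W = W, mu0 = mu0, tau = tau, B = B, gate_offset = gate_offset,
              eta_intercept = eta_intercept, eta_slope = eta_slope,
              psi = psi, read_pool = read_pool)
  class(cfg) <- "simulation_config"
  cfg
}

syn_mask <- function(cfg) {
  m <- matrix(FALSE, cfg$P, cfg$V)
  if (cfg$S > 0) m[, seq_len(cfg$S)] <- TRUE
  m
}

#' Two-component Gaussian mixture of effect scores
#'
#' Fits a two-component Gaussian mixture (EM, via mclust) to per-variant
#' scores and labels the "small-effect" mode as the component containing
#' more synonymous variants (tie broken by smaller absolute mean). Used to
#' parameterize the simulator's effect-size distribution from data.
#'
#' @param scores numeric vector of per-variant scores (NA dropped).
#' @param syn_flags logical vector, `TRUE` for synonymous variants.
#' @return list `p_small`, `mu_small`, `sigma_small`, `mu_large`,
#'   `sigma_large`.
#' @export
estimate_effect_mixture <- function(scores, syn_flags) {
  stopifnot(length(scores) == length(syn_flags))
  ok <- !is.na(scores)
  scores <- scores[ok]
  syn_flags <- syn_flags[ok]
  if (length(scores) < 20L) stop("need at least 20 scores to fit the mixture")
  if (sum(syn_flags) < 2L) stop("need at least 2 synonymous scores")
  if (sd(scores) == 0) stop("degenerate mixture: all scores identical")
  em_fit <- function(model) {
    # Mclust() re-evaluates mclustBIC() by name in the caller's frame, so
    # bind it locally (the package imports mclust rather than attaching it)
    mclustBIC <- mclust::mclustBIC
    mclust::Mclust(scores, G = 2, modelNames = model, verbose = FALSE)
  }
  fit <- em_fit("V")
  if (is.null(fit)) fit <- em_fit("E")
  if (is.null(fit)) stop("mixture EM did not converge")
  mean_g <- as.numeric(fit$parameters$mean)
  var_g <- fit$parameters$variance$sigmasq
  if (length(var_g) == 1L) var_g <- rep(var_g, 2)
  pro <- fit$parameters$pro
  nsyn <- vapply(1:2, function(g) sum(fit$classification[syn_flags] == g),
                 numeric(1))
  small <- if (nsyn[1] != nsyn[2]) which.max(nsyn) else which.min(abs(mean_g))
  large <- 3L - small
  list(p_small = pro[small], mu_small = mean_g[small],
       sigma_small = sqrt(var_g[small]), mu_large = mean_g[large],
       sigma_large = sqrt(var_g[large]))
}

#' Toggle an effect pattern to a target effect proportion
#'
#' Flips entries of a binary effect pattern `W`, chosen uniformly at
#' random, until the overall proportion of effects matches
#' `target_proportion` to within one entry. Synonymous slots (given by
#' `syn`) are never assigned an effect.
#'
#' @param W binary P x V matrix (1 = variant carries an effect).
#' @param target_proportion desired `mean(W)` over all slots, or `NULL` to
#'   return `W` unchanged.
#' @param syn logical matrix like `W` marking synonymous slots.
#' @param seed optional integer seed.
#' @return binary matrix with `round(target * length(W))` ones.
#' @export
build_effect_pattern <- function(W, target_proportion = NULL, syn = NULL,
                                 seed = NULL) {
  stopifnot(is.matrix(W), all(W %in% c(0, 1)))
  if (is.null(syn)) syn <- matrix(FALSE, nrow(W), ncol(W))
  W[syn] <- 0
  if (is.null(target_proportion)) return(W)
  if (target_proportion < 0 || target_proportion > 1) {
    stop("target effect proportion must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n_target <- round(target_proportion * length(W))
  n_now <- sum(W)
  if (n_target > sum(!syn)) {
    stop("target effect proportion exceeds available non-synonymous slots")
  }
  if (n_target > n_now) {
    pool <- which(W == 0 & !syn)
    W[sample_int(pool, n_target - n_now)] <- 1
  } else if (n_target < n_now) {
    pool <- which(W == 1)
    W[sample_int(pool, n_now - n_target)] <- 0
  }
  W
}

# sample() without the length-1 surprise
sample_int <- function(pool, n) {
  if (length(pool) == 1L) return(rep(pool, min(n, 1L)))
  sample(pool, n)
}

#' Sample ground-truth effect sizes
#'
#' For each position with at least one effect slot, draws a position mean
#' `theta_p` from the small-effect component with probability `p_small`,
#' otherwise from the large-effect component, truncated by rejection to
#' within 2 SDs of the component mean; slot effects are then
#' `Normal(theta_p, sigma_p)`. Slots with `W = 0` (including all synonymous
#' slots) get effect exactly 0.
#'
#' @param W binary effect pattern (P x V).
#' @param mixture effect mixture list (see [simulation_config()]).
#' @param sigma_p within-position effect SD.
#' @param seed optional integer seed.
#' @return numeric matrix of effects, same shape as `W`.
#' @export
sample_ground_truth <- function(W, mixture, sigma_p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- matrix(0, nrow(W), ncol(W))
  for (p in seq_len(nrow(W))) {
    idx <- which(W[p, ] == 1)
    if (length(idx) == 0L) next
    if (runif(1) < mixture$p_small) {
      theta <- rnorm_truncated(mixture$mu_small, mixture$sigma_small)
    } else {
      theta <- rnorm_truncated(mixture$mu_large, mixture$sigma_large)
    }
    beta[p, idx] <- rnorm(length(idx), theta, sigma_p)
  }
  beta
}

# rejection sampling of N(mu, sd) truncated to mu +/- 2 sd (no boundary atom)
rnorm_truncated <- function(mu, sd, width = 2) {
  repeat {
    x <- rnorm(1, mu, sd)
    if (abs(x - mu) <= width * sd) return(x)
  }
}

#' Wild-type fluorescence from pooled synonymous counts
#'
#' Pools the bin counts of all synonymous variants across replicates
#' (treating every synonymous observation as a draw from one distribution)
#' and fits a log-normal by binned maximum likelihood.
#'
#' @param data a [count_dataset()] containing synonymous variants.
#' @param gates a [gate_thresholds()].
#' @return list `mu0`, `tau`.
#' @export
estimate_wildtype_lognormal <- function(data, gates) {
  syn <- data$class == "synonymous"
  if (!any(syn)) stop("no synonymous variants to pool")
  y <- colSums(count_matrix(data)[syn, , drop = FALSE])
  fit <- fit_lognormal_bins(y, gates)
  if (!fit$converged) stop("pooled synonymous log-normal fit failed")
  list(mu0 = fit$mu, tau = fit$sigma)
}

#' Simulate the FACS sort: latent fluorescence, gates, sorted cells
#'
#' Draws `m` cells per (variant, replicate) from
#' `LogNormal(mu0 + beta_v + b_r, tau)`, where `b_r` are the R equidistant
#' replicate shifts in `[-B, B]`; sets the K-1 gate thresholds at equally
#' spaced quantiles of the pooled fluorescence draws, then shifts interior
#' thresholds by `gate_offset` on the log scale; and returns each variant's
#' sorted-cell bin counts and bin proportions.
#'
#' @param beta numeric vector (or matrix) of true effects, one per variant.
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return list: `p0` (n_variants x R x K bin-probability array), `cells`
#'   (same shape, counts summing to `m`), `gates`, `b_r`.
#' @export
simulate_sort <- function(beta, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- as.vector(t(beta))
  nv <- length(beta)
  R <- config$R
  K <- config$K
  m <- config$m
  b_r <- if (R == 1) 0 else seq(-config$B, config$B, length.out = R)
  f <- array(NA_real_, dim = c(nv, R, m))
  for (r in seq_len(R)) {
    f[, r, ] <- matrix(stats::rlnorm(nv * m,
                                     meanlog = config$mu0 + beta + b_r[r],
                                     sdlog = config$tau), nrow = nv)
  }
  cuts <- as.numeric(quantile(f, probs = seq_len(K - 1) / K))
  cuts <- cuts * exp(config$gate_offset)
  cells <- array(0L, dim = c(nv, R, K))
  for (r in seq_len(R)) {
    bin <- findInterval(f[, r, ], cuts) + 1L
    dim(bin) <- c(nv, m)
    for (v in seq_len(nv)) cells[v, r, ] <- tabulate(bin[v, ], nbins = K)
  }
  list(p0 = cells / m, cells = cells, gates = gates_from_interior(cuts),
       b_r = b_r)
}

#' Estimate the variant overdispersion trend from synonymous counts
#'
#' Pools synonymous bin proportions `q`, estimates a per-synonymous-variant
#' Dirichlet-multinomial concentration `eta_v` by Brent's method on
#' (0, 1000) with bin proportions fixed at `q`, and regresses the estimates
#' on each variant's mean replicate read count by ordinary least squares,
#' giving the linear trend `eta(N) = intercept + slope * N`.
#'
#' @param data a [count_dataset()] containing synonymous variants (>= 5).
#' @return list: `q` (pooled proportions), `eta` (per-variant estimates
#'   with mean counts), `intercept`, `slope`.
#' @export
estimate_eta_trend <- function(data) {
  syn <- which(data$class == "synonymous")
  if (length(unique(data$variant[syn])) < 5L) {
    stop("need at least 5 synonymous variants to estimate the trend")
  }
  y <- count_matrix(data)[syn, , drop = FALSE]
  q <- colSums(y) / sum(y)
  if (any(q <= 0)) q <- (colSums(y) + 0.5) / sum(colSums(y) + 0.5)
  vs <- data$variant[syn]
  uv <- unique(vs)
  eta_hat <- numeric(length(uv))
  nbar <- numeric(length(uv))
  at_bound <- FALSE
  for (i in seq_along(uv)) {
    rowsi <- y[vs == uv[i], , drop = FALSE]
    nll <- function(eta) {
      -sum(apply(rowsi, 1, function(yy)
        dm_log_density(yy, sum(yy), eta, q)))
    }
    opt <- optimize(nll, interval = c(1e-4, 1000))
    eta_hat[i] <- opt$minimum
    if (opt$minimum > 0.999 * 1000 || opt$minimum < 1e-3) at_bound <- TRUE
    nbar[i] <- mean(rowSums(rowsi))
  }
  if (at_bound) {
    warning("eta estimate at a Brent bound for some variant(s); ",
            "counts may be nearly multinomial or degenerate")
  }
  ols <- lm(eta_hat ~ nbar)
  slope <- unname(coef(ols)[2])
  intercept <- unname(coef(ols)[1])
  if (is.na(slope)) {  # constant read depth: trend degenerates to the mean
    slope <- 0
    intercept <- mean(eta_hat)
  }
  list(q = q,
       eta = data.frame(variant = uv, eta = eta_hat, mean_count = nbar),
       intercept = intercept, slope = slope)
}

# one draw from DirichletMultinomial(size, alpha); alpha entries of 0 are
# structural zeros
rdirmult <- function(size, alpha) {
  if (size == 0) return(rep(0L, length(alpha)))
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) {
    pr <- as.numeric(alpha > 0)
    pr <- pr / sum(pr)
  } else {
    pr <- g / sum(g)
  }
  as.integer(rmultinom(1, size, pr))
}

#' Sample observed reads per variant
#'
#' For each (variant, replicate), resamples a read total from `read_pool`
#' (with replacement), evaluates the overdispersion trend at the variant's
#' mean read count, and draws bin reads from
#' `DirichletMultinomial(N*, eta_v * p0_vr)`.
#'
#' @param p0 n_variants x R x K array of latent bin probabilities.
#' @param config a [simulation_config()] (supplies the eta trend and, if
#'   `read_pool` is `NULL`, the synthetic read-total model).
#' @param seed optional integer seed.
#' @return list: `counts` (n_variants x R x K integer array), `N` (read
#'   totals), `eta` (per-variant overdispersion used).
#' @export
sample_observed_counts <- function(p0, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nv <- dim(p0)[1]
  R <- dim(p0)[2]
  K <- dim(p0)[3]
  pool <- config$read_pool
  if (is.null(pool)) {
    Nvr <- matrix(rnbinom(nv * R, mu = config$L / (nv * R), size = 10),
                  nv, R)
  } else {
    if (length(pool) == 0L) stop("empty read pool")
    Nvr <- matrix(sample(pool, nv * R, replace = TRUE), nv, R)
  }
  nbar <- rowMeans(Nvr)
  eta <- pmax(config$eta_intercept + config$eta_slope * nbar, 1e-2)
  counts <- array(0L, dim = c(nv, R, K))
  for (v in seq_len(nv)) {
    for (r in seq_len(R)) {
      counts[v, r, ] <- rdirmult(Nvr[v, r], eta[v] * p0[v, r, ])
    }
  }
  list(counts = counts, N = Nvr, eta = eta)
}

#' Add bin-level read overdispersion
#'
#' Alternative read model stressing PCR amplification bias: within each
#' (replicate, bin), variant read proportions are taken from the sorted
#' cell counts and reads are drawn once per bin from
#' `DirichletMultinomial(N_K, psi_k * p)`, with `N_K = L / (K * R)` reads
#' sequenced per bin and replicate. Smaller `psi_k` means noisier bins.
#'
#' @param cells n_variants x R x K array of sorted cell counts.
#' @param psi length-K positive bin overdispersion.
#' @param L total reads for the experiment.
#' @param seed optional integer seed.
#' @return n_variants x R x K integer array of observed reads.
#' @export
apply_bin_overdispersion <- function(cells, psi, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nv <- dim(cells)[1]
  R <- dim(cells)[2]
  K <- dim(cells)[3]
  stopifnot(length(psi) == K, all(psi > 0))
  N_K <- round(L / (K * R))
  out <- array(0L, dim = c(nv, R, K))
  for (r in seq_len(R)) {
    for (k in seq_len(K)) {
      tot <- sum(cells[, r, k])
      if (tot == 0) {
        warning("replicate ", r, ", bin ", k,
                ": no sorted cells; emitting zero reads")
        next
      }
      p <- cells[, r, k] / tot
      out[, r, k] <- rdirmult(N_K, psi[k] * p)
    }
  }
  out
}

#' Simulate a complete sort-seq dataset with ground truth
#'
#' Chains the generative stages: effect pattern, ground-truth effects,
#' latent sort, and observed reads (per-variant Dirichlet-multinomial, or
#' per-bin when `config$psi` is set). Fully reproducible from `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return a `simulated_dataset` list: `counts` (a [count_dataset()]),
#'   `truth` (per-variant `beta_true` and `is_effect`), `gates`, `p0`,
#'   `W`, `config`, `seed`.
#' @export
simulate_dataset <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  syn <- syn_mask(config)
  W <- config$W
  if (is.null(W)) {
    W <- build_effect_pattern(matrix(0, config$P, config$V),
                              target_proportion = config$effect_proportion,
                              syn = syn)
  } else {
    W <- build_effect_pattern(W, syn = syn)
  }
  beta <- sample_ground_truth(W, config$mixture, config$sigma_p)
  sorted <- simulate_sort(beta, config)
  if (is.null(config$psi)) {
    obs <- sample_observed_counts(sorted$p0, config)
    counts <- obs$counts
  } else {
    counts <- apply_bin_overdispersion(sorted$cells, config$psi, config$L)
  }
  flat <- flatten_sim(counts, beta, syn, config)
  structure(list(counts = flat$data, truth = flat$truth,
                 gates = sorted$gates, p0 = sorted$p0, W = W,
                 config = config, seed = seed),
            class = "simulated_dataset")
}

flatten_sim <- function(counts, beta, syn, config) {
  P <- config$P
  V <- config$V
  R <- config$R
  K <- config$K
  slot <- function(j) {
    ifelse(j <= config$S, paste0("syn", j), paste0("mis", j - config$S))
  }
  grid <- expand.grid(j = seq_len(V), p = seq_len(P))  # row-major like t(W)
  variant <- paste0("p", grid$p, "_", slot(grid$j))
  vclass <- ifelse(grid$j <= config$S, "synonymous", "missense")
  beta_v <- as.vector(t(beta))
  rows <- do.call(rbind, lapply(seq_len(R), function(r) {
    df <- data.frame(variant = variant, position = grid$p,
                     mutation = slot(grid$j), class = vclass,
                     replicate = paste0("R", r))
    cnt <- counts[, r, , drop = FALSE]
    dim(cnt) <- c(length(variant), K)
    cbind(df, as.data.frame(setNames(as.data.frame(cnt), count_cols(K))))
  }))
  data <- count_dataset(rows, k_bins = K)
  truth <- data.frame(variant = variant, position = grid$p, class = vclass,
                      beta_true = beta_v, is_effect = beta_v != 0)
  list(data = data, truth = truth)
}

#' Estimate a simulation configuration from a seed dataset
#'
#' Summarizes a real (or pseudo-real) count dataset into simulator
#' parameters: effect mixture from the ML log-normal scores, effect pattern
#' from mean-bin discoveries at the 2-SD synonymous cutoff, within-position
#' effect SD from the ML scores of effect variants, wild-type log-normal
#' from pooled synonymous counts, overdispersion trend from the synonymous
#' Dirichlet-multinomial fits, and the read-total pool from the observed
#' row sums.
#'
#' @param data a [count_dataset()] of raw counts.
#' @param gates a [gate_thresholds()] (needed for the ML fits).
#' @param m,P,... overrides passed on to [simulation_config()].
#' @return a [simulation_config()].
#' @export
config_from_data <- function(data, gates, m = 200, P = 100, ...) {
  K <- n_bins(data)
  ml <- ml_lognormal_scores(data, gates)
  mix <- estimate_effect_mixture(ml$score, ml$class == "synonymous")
  mb <- synonymous_null_threshold(mean_bin_scores(data))
  wt <- estimate_wildtype_lognormal(data, gates)
  tr <- estimate_eta_trend(data)
  y <- count_matrix(data)
  read_pool <- rowSums(y)
  # effect pattern: per-position discovery flags from the mean-bin scorer
  mis <- mb[mb$class != "synonymous", ]
  eff_by_pos <- split(mis$discovery, mis$position)
  syn_by_pos <- table(mb$position[mb$class == "synonymous"])
  n_syn <- max(1L, round(mean(as.numeric(syn_by_pos))))
  n_mis <- max(vapply(eff_by_pos, length, integer(1)))
  V <- n_syn + n_mis
  W <- matrix(0, length(eff_by_pos), V)
  for (i in seq_along(eff_by_pos)) {
    flags <- eff_by_pos[[i]]
    W[i, n_syn + seq_along(flags)] <- as.numeric(flags)
  }
  # within-position SD of ML scores among effect variants
  eff <- merge(mis[mis$discovery, c("variant", "position")],
               ml[, c("variant", "score")], by = "variant")
  pos_sd <- tapply(eff$score, eff$position, sd)
  sigma_p <- mean(pos_sd, na.rm = TRUE)
  if (!is.finite(sigma_p) || sigma_p <= 0) sigma_p <- 0.3
  R <- length(unique(data$replicate))
  simulation_config(P = nrow(W), variants_per_position = V,
                    syn_per_position = n_syn, R = R, K = K,
                    L = sum(y), m = m, mixture = mix, sigma_p = sigma_p,
                    W = W, mu0 = wt$mu0, tau = wt$tau,
                    eta_intercept = tr$intercept, eta_slope = tr$slope,
                    read_pool = read_pool, ...)
}
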
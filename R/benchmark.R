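#' False discovery rate and sensitivity of a discovery set
#'
#' `FDR = false discoveries / max(1, discoveries)` (so an empty discovery
#' set has FDR 0) and `sensitivity = true discoveries / max(1, true
#' effects)`.
#'
#' @param discoveries logical vector of discovery calls.
#' @param truth logical vector of the same length, `TRUE` for real effects.
#' @return named numeric vector `c(fdr, sensitivity)`.
#' @export
fdr_sensitivity <- function(discoveries, truth) {
  stopifnot(length(discoveries) == length(truth))
  discoveries <- as.logical(discoveries)
  truth <- as.logical(truth)
  n_disc <- sum(discoveries)
  c(fdr = sum(discoveries & !truth) / max(1, n_disc),
    sensitivity = sum(discoveries & truth) / max(1, sum(truth)))
}

#' Built-in scorers for benchmarking
#'
#' Each scorer maps a `simulated_dataset` (or a [count_dataset()] plus
#' gates) to named per-variant discovery flags at the common 95%-certainty
#' threshold: lfsr < 0.05 for the Bayesian model, two-sided p < 0.05
#' against the synonymous null for the baselines. Variants removed by the
#' count filter are reported as non-discoveries.
#'
#' @param method one of `"bayes"`, `"meanbin"`, `"ml"`.
#' @param min_total,pseudocount preprocessing, see
#'   [filter_and_pseudocount()].
#' @param ... for `"bayes"`: passed to [fit_effects()] (e.g. `chains`,
#'   `warmup`, `samples`, `use_position_hierarchy`).
#' @return a function `(data, gates, seed)` returning a named logical
#'   vector of discoveries.
#' @export
make_scorer <- function(method = c("bayes", "meanbin", "ml"),
                        min_total = 15, pseudocount = 0.5, ...) {
  method <- match.arg(method)
  extra <- list(...)
  function(data, gates = NULL, seed = 1) {
    kept <- filter_and_pseudocount(data, min_total = min_total,
                                   pseudocount = if (method == "bayes")
                                     pseudocount else 0)
    tab <- switch(method,
      bayes = do.call(score_variants,
                      c(list(data = kept, seed = seed), extra)),
      meanbin = synonymous_null_threshold(mean_bin_scores(kept)),
      ml = {
        if (is.null(gates)) stop("the ml scorer needs gate thresholds")
        synonymous_null_threshold(ml_lognormal_scores(kept, gates))
      })
    setNames(tab$discovery, tab$variant)
  }
}

#' Repeated-simulation FDR/sensitivity benchmark
#'
#' For every configuration and repeat, simulates a dataset with a distinct
#' seed, runs every method, and scores discoveries against the ground
#' truth. Synonymous variants are excluded from the evaluation set (they
#' are the controls, not the test set). A method failing on a repeat is
#' recorded as `NA`, never dropped silently.
#'
#' @param configs list of [simulation_config()] objects (optionally named).
#' @param methods character vector of built-in scorers (`"bayes"`,
#'   `"meanbin"`, `"ml"`) or a named list of scorer functions
#'   `(data, gates, seed) -> named logical`.
#' @param n_repeats repeats per configuration (default 10).
#' @param seed master seed; repeat seeds are derived from it.
#' @param scorer_args named list of extra arguments for [make_scorer()]
#'   when `methods` is a character vector (e.g. MCMC settings).
#' @return list with `results` (long data frame: one row per config x
#'   method x repeat) and `summary` (mean and SE per config x method).
#' @export
run_benchmark_grid <- function(configs, methods = c("bayes", "meanbin"),
                               n_repeats = 10, seed = 1,
                               scorer_args = list()) {
  if (inherits(configs, "simulation_config")) configs <- list(configs)
  if (is.null(names(configs))) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  if (is.character(methods)) {
    methods <- setNames(lapply(methods, function(m)
      do.call(make_scorer, c(list(method = m), scorer_args))), methods)
  }
  set.seed(seed)
  sim_seeds <- matrix(sample.int(1e6, length(configs) * n_repeats),
                      nrow = length(configs))
  rows <- list()
  for (ci in seq_along(configs)) {
    for (it in seq_len(n_repeats)) {
      sim <- simulate_dataset(configs[[ci]], seed = sim_seeds[ci, it])
      eval_set <- sim$truth$class != "synonymous"
      truth <- sim$truth$is_effect[eval_set]
      vids <- sim$truth$variant[eval_set]
      for (mi in seq_along(methods)) {
        res <- tryCatch({
          disc <- methods[[mi]](sim$counts, gates = sim$gates,
                                seed = sim_seeds[ci, it] + 1L)
          flags <- unname(disc[vids])
          flags[is.na(flags)] <- FALSE
          fdr_sensitivity(flags, truth)
        }, error = function(e) {
          warning("method '", names(methods)[mi], "' failed on ",
                  names(configs)[ci], " repeat ", it, ": ",
                  conditionMessage(e))
          c(fdr = NA_real_, sensitivity = NA_real_)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          config = names(configs)[ci], method = names(methods)[mi],
          repeat_id = it, seed = sim_seeds[ci, it],
          fdr = res[["fdr"]], sensitivity = res[["sensitivity"]])
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- function(x) c(mean = mean(x, na.rm = TRUE),
                       se = sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
  summ <- do.call(rbind, lapply(
    split(results, list(results$config, results$method), drop = TRUE),
    function(d) {
      f <- agg(d$fdr)
      s <- agg(d$sensitivity)
      data.frame(config = d$config[1], method = d$method[1],
                 n_repeats = nrow(d), fdr_mean = f[["mean"]],
                 fdr_se = f[["se"]], sensitivity_mean = s[["mean"]],
                 sensitivity_se = s[["se"]])
    }))
  rownames(summ) <- NULL
  list(results = results, summary = summ)
}

#' Empirical FDR by synonymous masking
#'
#' Hides a fraction of the synonymous variants by relabeling them as
#' missense (they keep their position, and thus any position-level
#' shrinkage), rescored with only the remaining synonymous variants as
#' controls. Since masked variants are wild-type-like by construction, the
#' fraction of them called significant estimates the method's FDR on null
#' variants. Repeated over `n_iter` random masks.
#'
#' @param data a [count_dataset()] with at least 5 synonymous variants.
#' @param scorer a scorer function `(data, gates, seed) -> named logical`
#'   (see [make_scorer()]).
#' @param gates optional [gate_thresholds()] forwarded to the scorer.
#' @param mask_fraction fraction of synonymous variants masked per
#'   iteration (default 0.2).
#' @param n_iter number of masks (default 10).
#' @param seed master seed.
#' @return list: `fdr_mean`, `fdr_se`, `per_iter` (data frame with the
#'   masked count and FDR of each iteration).
#' @export
synonymous_masking_fdr <- function(data, scorer, gates = NULL,
                                   mask_fraction = 0.2, n_iter = 10,
                                   seed = 1) {
  syn_variants <- unique(data$variant[data$class == "synonymous"])
  if (length(syn_variants) < 5L) {
    stop("need at least 5 synonymous variants to mask")
  }
  n_mask <- max(1L, round(mask_fraction * length(syn_variants)))
  if (length(syn_variants) - n_mask < 2L) {
    stop("masking would leave fewer than 2 synonymous controls")
  }
  set.seed(seed)
  mask_sets <- lapply(seq_len(n_iter), function(i)
    sample(syn_variants, n_mask))
  iter_seeds <- sample.int(1e6, n_iter)
  fdr <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    masked <- mask_sets[[i]]
    relabeled <- as.data.frame(data)
    hit <- relabeled$variant %in% masked
    stopifnot(!any(relabeled$class[hit] != "synonymous"))
    relabeled$class[hit] <- "missense"
    relabeled <- count_dataset(relabeled, k_bins = n_bins(data))
    disc <- scorer(relabeled, gates = gates, seed = iter_seeds[i])
    called <- disc[masked]
    called[is.na(called)] <- FALSE
    fdr[i] <- mean(called)
  }
  list(fdr_mean = mean(fdr), fdr_se = sd(fdr) / sqrt(n_iter),
       per_iter = data.frame(iter = seq_len(n_iter), n_masked = n_mask,
                             fdr = fdr))
}
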
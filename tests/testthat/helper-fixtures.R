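# Small in-code fixtures shared across test files.

# count_dataset from a counts matrix (rows are variant x replicate in the
# order given); metadata defaults to one replicate per row block.
make_counts <- function(counts, variant, replicate, position = NULL,
                        class = NULL, mutation = NULL) {
  counts <- as.matrix(counts)
  k <- ncol(counts)
  n <- nrow(counts)
  df <- data.frame(variant = variant,
                   position = position %||% match(variant, unique(variant)),
                   mutation = mutation %||% variant,
                   class = class %||% "missense",
                   replicate = replicate)
  df <- cbind(df, as.data.frame(counts))
  names(df)[5 + seq_len(k)] <- paste0("c", seq_len(k))
  suppressWarnings(count_dataset(df, k_bins = k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny multinomial dataset around a common baseline: nv variants (first
# n_syn synonymous), R replicates, K bins; all true effects zero
tiny_null_counts <- function(nv = 8, n_syn = 3, R = 2, K = 4, N = 400,
                             seed = 1) {
  set.seed(seed)
  q <- rep(1 / K, K)
  rows <- expand.grid(v = seq_len(nv), r = seq_len(R))
  y <- t(vapply(seq_len(nrow(rows)),
                function(i) as.numeric(rmultinom(1, N, q)), numeric(K)))
  make_counts(y + 0.5,
              variant = paste0("v", rows$v),
              replicate = paste0("R", rows$r),
              position = ((rows$v - 1) %/% 2) + 1,
              class = ifelse(rows$v <= n_syn, "synonymous", "missense"))
}

# fake posterior_draws for bias-correction tests: beta is a D x V matrix
fake_draws <- function(beta, syn_idx, class = NULL) {
  V <- ncol(beta)
  vinfo <- data.frame(variant = colnames(beta) %||% paste0("v", seq_len(V)),
                      position = seq_len(V), mutation = "m",
                      class = class %||% ifelse(seq_len(V) %in% syn_idx,
                                                "synonymous", "missense"))
  colnames(beta) <- vinfo$variant
  structure(list(beta = beta, variants = vinfo, syn_idx = syn_idx,
                 n_draws = nrow(beta)),
            class = "posterior_draws")
}

# fast MCMC settings for unit tests
fast_mcmc <- list(chains = 1, warmup = 250, samples = 150)
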
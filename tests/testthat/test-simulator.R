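test_that("simulation config validates its parameters", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(K = 1))
  expect_error(simulation_config(syn_per_position = 6,
                                 variants_per_position = 6))
  expect_error(simulation_config(psi = c(1, 1)))  # wrong length for K = 4
})

test_that("effect pattern toggling hits the target count exactly", {
  set.seed(21)
  syn <- matrix(FALSE, 100, 20)
  syn[, 1] <- TRUE
  W <- matrix(0, 100, 20)
  W[cbind(sample(1:100, 400, TRUE), sample(2:20, 400, TRUE))] <- 1
  start_prop <- mean(W)
  expect_identical(build_effect_pattern(W, NULL, syn), W)
  expect_equal(sum(build_effect_pattern(W, 0, syn)), 0)
  up <- build_effect_pattern(W, 0.4, syn, seed = 1)
  expect_equal(mean(up), 0.4, tolerance = 1 / length(W))
  expect_true(all(up[W == 1] == 1))      # raising only adds effects
  expect_true(all(up[, 1] == 0))         # synonymous slots stay zero
  down <- build_effect_pattern(W, 0.1, syn, seed = 1)
  expect_equal(mean(down), 0.1, tolerance = 1 / length(W))
  expect_true(all(W[down == 1] == 1))    # lowering only removes effects
  expect_error(build_effect_pattern(W, 1.5, syn), "\\[0, 1\\]")
  expect_error(build_effect_pattern(W, 0.99, syn), "slots")
})

test_that("toggled entries are chosen uniformly across slots", {
  syn <- matrix(FALSE, 4, 5)
  syn[, 1] <- TRUE
  W <- matrix(0, 4, 5)
  counts <- matrix(0, 4, 5)
  set.seed(22)
  n_rep <- 600
  for (i in seq_len(n_rep)) {
    counts <- counts + build_effect_pattern(W, 0.25, syn)
  }
  # each of the 16 eligible (non-synonymous) slots picked equally often
  expect_true(all(counts[syn] == 0))
  eligible <- as.vector(counts[!syn])
  expect_gt(suppressWarnings(
    chisq.test(eligible, p = rep(1 / 16, 16))$p.value), 1e-4)
})

test_that("ground-truth effects respect the mixture and truncation", {
  mix <- list(p_small = 0.7, mu_small = 0, sigma_small = 0.15,
              mu_large = -1.5, sigma_large = 0.5)
  W <- matrix(1, 2000, 2)
  # sigma_p = 0: both slots at a position equal the position mean
  beta <- sample_ground_truth(W, mix, sigma_p = 0, seed = 23)
  expect_equal(beta[, 1], beta[, 2])
  theta <- beta[, 1]
  in_small <- abs(theta - mix$mu_small) <= 2 * mix$sigma_small
  in_large <- abs(theta - mix$mu_large) <= 2 * mix$sigma_large
  expect_true(all(in_small | in_large))   # 2-SD truncation, no escapes
  p_hat <- mean(in_small & !in_large)
  expect_lt(abs(p_hat - mix$p_small), 3 * sqrt(0.7 * 0.3 / 2000) + 0.01)
  # W = 0 rows are exactly zero
  W0 <- W
  W0[1:100, ] <- 0
  beta0 <- sample_ground_truth(W0, mix, sigma_p = 0.3, seed = 24)
  expect_true(all(beta0[1:100, ] == 0))
})

test_that("the sort places replicate shifts and quantile gates correctly", {
  cfg <- simulation_config(P = 10, variants_per_position = 4,
                           syn_per_position = 1, R = 3, K = 4, m = 200,
                           B = 0.3)
  beta <- matrix(0, 10, 4)
  s <- simulate_sort(beta, cfg, seed = 25)
  expect_equal(s$b_r, c(-0.3, 0, 0.3))
  expect_s3_class(s$gates, "gate_thresholds")
  expect_true(all(diff(s$gates$lower) > 0))
  # with B = 0 and no effects, each bin holds ~ 1/K of every variant's cells
  cfg0 <- simulation_config(P = 10, variants_per_position = 4,
                            syn_per_position = 1, R = 2, K = 4, m = 500)
  s0 <- simulate_sort(matrix(0, 10, 4), cfg0, seed = 26)
  pooled <- apply(s0$p0, 3, mean)
  expect_true(all(abs(pooled - 0.25) < 0.02))
  expect_equal(apply(s0$cells, c(1, 2), sum),
               matrix(500L, 40, 2), ignore_attr = TRUE)
  # a large positive effect concentrates cells in the top bin
  bbig <- matrix(0, 10, 4)
  bbig[1, 2] <- 5
  sbig <- simulate_sort(bbig, cfg0, seed = 27)
  expect_gt(sbig$p0[2, 1, 4], 0.95)
})

test_that("gate offset shifts interior thresholds on the log scale", {
  cfg <- simulation_config(P = 5, variants_per_position = 4,
                           syn_per_position = 1, K = 4, m = 100,
                           gate_offset = 0.2)
  cfg0 <- simulation_config(P = 5, variants_per_position = 4,
                            syn_per_position = 1, K = 4, m = 100)
  s1 <- simulate_sort(matrix(0, 5, 4), cfg, seed = 28)
  s0 <- simulate_sort(matrix(0, 5, 4), cfg0, seed = 28)
  interior1 <- s1$gates$lower[-1]
  interior0 <- s0$gates$lower[-1]
  expect_equal(log(interior1) - log(interior0), rep(0.2, 3),
               tolerance = 1e-12)
})

test_that("eta estimates stay inside the Brent bounds and recover truth", {
  set.seed(29)
  q <- rep(0.25, 4)
  eta <- 50
  rows <- expand.grid(v = 1:12, r = 1:8)
  y <- t(vapply(seq_len(nrow(rows)), function(i) {
    g <- rgamma(4, eta * q)
    as.numeric(rmultinom(1, 3000, g / sum(g)))
  }, numeric(4)))
  d <- make_counts(y, variant = paste0("s", rows$v),
                   replicate = paste0("R", rows$r),
                   class = "synonymous")
  tr <- estimate_eta_trend(d)
  expect_true(all(tr$eta$eta > 0 & tr$eta$eta < 1000))
  expect_lt(abs(mean(tr$eta$eta) - eta), 15)
  expect_lt(max(abs(tr$q - 0.25)), 0.02)
})

test_that("nearly multinomial counts push eta to the upper bound", {
  set.seed(30)
  y <- t(vapply(1:40, function(i)
    as.numeric(rmultinom(1, 5000, rep(0.25, 4))), numeric(4)))
  d <- make_counts(y, variant = paste0("s", rep(1:5, each = 8)),
                   replicate = paste0("R", rep(1:8, 5)),
                   class = "synonymous")
  expect_warning(tr <- estimate_eta_trend(d), "bound")
  expect_true(all(tr$eta$eta > 900))
})

test_that("observed counts honor read totals, the trend, and the seed", {
  cfg <- simulation_config(P = 4, variants_per_position = 4,
                           syn_per_position = 1, R = 2, K = 4, m = 200,
                           L = 2e5, eta_intercept = 5, eta_slope = 0)
  s <- simulate_sort(matrix(0, 4, 4), cfg, seed = 31)
  o1 <- sample_observed_counts(s$p0, cfg, seed = 32)
  o2 <- sample_observed_counts(s$p0, cfg, seed = 32)
  expect_identical(o1$counts, o2$counts)
  expect_equal(apply(o1$counts, c(1, 2), sum), o1$N, ignore_attr = TRUE)
  expect_true(all(o1$eta == 5))
  # huge eta: DM collapses to multinomial around p0
  cfg_big <- simulation_config(P = 4, variants_per_position = 4,
                               syn_per_position = 1, R = 2, K = 4, m = 200,
                               L = 8e6, eta_intercept = 1e6, eta_slope = 0)
  ob <- sample_observed_counts(s$p0, cfg_big, seed = 33)
  prop <- ob$counts[1, 1, ] / sum(ob$counts[1, 1, ])
  n1 <- sum(ob$counts[1, 1, ])
  se <- sqrt(s$p0[1, 1, ] * (1 - s$p0[1, 1, ]) / n1)
  expect_true(all(abs(prop - s$p0[1, 1, ]) < 5 * se + 0.01))
  # read pool resampling stays inside the pool
  cfg_pool <- simulation_config(P = 4, variants_per_position = 4,
                                syn_per_position = 1, R = 2, K = 4,
                                read_pool = c(100, 200))
  op <- sample_observed_counts(s$p0, cfg_pool, seed = 34)
  expect_true(all(op$N %in% c(100, 200)))
})

test_that("bin overdispersion keeps per-bin totals and orders variance", {
  cfg <- simulation_config(P = 5, variants_per_position = 4,
                           syn_per_position = 1, R = 2, K = 4, m = 200)
  s <- simulate_sort(matrix(0, 5, 4), cfg, seed = 35)
  L <- 4e4
  obs <- apply_bin_overdispersion(s$cells, psi = rep(10, 4), L = L,
                                  seed = 36)
  expect_equal(apply(obs, c(2, 3), sum),
               matrix(round(L / 8), 2, 4), ignore_attr = TRUE)
  # psi huge: read shares track cell shares
  obs_big <- apply_bin_overdispersion(s$cells, psi = rep(1e6, 4), L = L,
                                      seed = 37)
  cell_share <- s$cells[, 1, 1] / sum(s$cells[, 1, 1])
  read_share <- obs_big[, 1, 1] / sum(obs_big[, 1, 1])
  expect_lt(max(abs(read_share - cell_share)), 0.02)
  # smaller psi inflates the across-run variance of a variant's reads
  var_at <- function(psi) {
    reads <- vapply(1:60, function(i)
      apply_bin_overdispersion(s$cells, psi = rep(psi, 4), L = L,
                               seed = 100 + i)[1, 1, 1], numeric(1))
    var(reads)
  }
  expect_gt(var_at(2), var_at(1000))
})

test_that("simulated datasets satisfy their own invariants", {
  cfg <- simulation_config(P = 20, variants_per_position = 5,
                           syn_per_position = 1, R = 3, K = 4, m = 100,
                           L = 3e5, effect_proportion = 0)
  sim <- simulate_dataset(cfg, seed = 38)
  expect_s3_class(sim$counts, "count_dataset")
  expect_true(all(sim$truth$beta_true == 0))
  expect_true(all(sim$truth$beta_true[sim$truth$class == "synonymous"] == 0))
  expect_equal(nrow(sim$counts), 20 * 5 * 3)
  # same seed, same dataset
  sim2 <- simulate_dataset(cfg, seed = 38)
  expect_identical(count_matrix(sim2$counts), count_matrix(sim$counts))
  # synonymous bin-1 share tracks the gate construction (1/K here)
  syn_rows <- sim$counts$class == "synonymous"
  y <- count_matrix(sim$counts)[syn_rows, ]
  expect_lt(abs(sum(y[, 1]) / sum(y) - 0.25), 0.03)
  # effect datasets mark truth labels consistently
  cfg_eff <- simulation_config(P = 20, variants_per_position = 5,
                               syn_per_position = 1, R = 2, K = 4, m = 100,
                               L = 3e5, effect_proportion = 0.4)
  sim_eff <- simulate_dataset(cfg_eff, seed = 39)
  expect_equal(mean(sim_eff$W), 0.4, tolerance = 1 / 100)
  expect_identical(sim_eff$truth$is_effect, sim_eff$truth$beta_true != 0)
  # bin-overdispersion route: per-bin totals fixed
  cfg_psi <- simulation_config(P = 10, variants_per_position = 4,
                               syn_per_position = 1, R = 2, K = 4, m = 100,
                               L = 8e4, psi = rep(20, 4),
                               effect_proportion = 0)
  sim_psi <- simulate_dataset(cfg_psi, seed = 40)
  y_psi <- count_matrix(sim_psi$counts)
  r1 <- sim_psi$counts$replicate == "R1"
  expect_equal(unname(colSums(y_psi[r1, ])), rep(round(8e4 / 8), 4))
})

test_that("the effect mixture fit labels the synonymous-rich mode as small", {
  set.seed(41)
  scores <- c(rnorm(1400, 0, 0.1), rnorm(600, -2, 0.3))
  syn <- c(rep(TRUE, 100), rep(FALSE, 1900))  # synonymous live in the 0 mode
  mix <- estimate_effect_mixture(scores, syn)
  expect_lt(abs(mix$p_small - 0.7), 0.05)
  expect_lt(abs(mix$mu_small - 0), 0.05)
  expect_lt(abs(mix$mu_large - (-2)), 0.1)
  expect_lt(abs(mix$sigma_large - 0.3), 0.1)
  expect_error(estimate_effect_mixture(rep(1, 100), rep(TRUE, 100)),
               "degenerate")
  expect_error(estimate_effect_mixture(scores[1:10], syn[1:10]),
               "at least 20")
})

test_that("a configuration can be estimated from a seed dataset", {
  cfg <- simulation_config(P = 30, variants_per_position = 6,
                           syn_per_position = 1, R = 3, K = 4, m = 200,
                           L = 8e5, effect_proportion = 0.4)
  sim <- simulate_dataset(cfg, seed = 42)
  est <- config_from_data(sim$counts, sim$gates)
  expect_s3_class(est, "simulation_config")
  expect_equal(est$K, 4)
  expect_equal(est$R, 3)
  expect_gt(est$mixture$p_small, 0.3)
  expect_lt(abs(est$mu0 - 5), 0.5)
  expect_lt(abs(est$tau - 0.5), 0.15)
  expect_true(length(est$read_pool) == nrow(sim$counts))
  # and the estimated configuration itself simulates end to end
  resim <- simulate_dataset(est, seed = 43)
  expect_s3_class(resim$counts, "count_dataset")
})

test_that("pooled wild-type fit recovers the synonymous log-normal", {
  set.seed(44)
  mu0 <- 5
  tau <- 0.4
  interior <- exp(mu0 + tau * qnorm(c(0.25, 0.5, 0.75)))
  gates <- gates_from_interior(interior)
  mk <- function(n) tabulate(findInterval(rlnorm(n, mu0, tau),
                                          interior) + 1L, nbins = 4)
  y <- rbind(mk(3e5), mk(3e5), mk(4e5))
  d <- make_counts(y, variant = c("s1", "s2", "s3"), replicate = "R1",
                   class = "synonymous")
  wt <- estimate_wildtype_lognormal(d, gates)
  expect_lt(abs(wt$mu0 - mu0), 0.01)
  expect_lt(abs(wt$tau - tau), 0.01)
  # pooling two identical variants equals one at double depth
  d2 <- make_counts(rbind(mk(1e5)), variant = "s1", replicate = "R1",
                    class = "synonymous")
  y1 <- count_matrix(d2)[1, ]
  dd <- make_counts(rbind(y1, y1), variant = c("s1", "s2"),
                    replicate = "R1", class = "synonymous")
  d_double <- make_counts(rbind(2 * y1), variant = "s1", replicate = "R1",
                          class = "synonymous")
  expect_equal(estimate_wildtype_lognormal(dd, gates)$mu0,
               estimate_wildtype_lognormal(d_double, gates)$mu0,
               tolerance = 1e-6)
  expect_error(estimate_wildtype_lognormal(
    make_counts(rbind(c(1, 1, 1, 1)), variant = "m", replicate = "R1",
                class = "missense"), gates), "synonymous")
})
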
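---
title: "Scoring variant effects from FACS sort-seq bin counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring variant effects from FACS sort-seq bin counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscore)
```

## The measurement problem

In a FACS-based deep mutational scanning (DMS) screen, a pooled library of
protein variants is expressed in cells, the cells are sorted into K
fluorescence gates (bins), and each bin is sequenced. The data that reach
the analyst are, for every variant and replicate, K read counts — a coarse,
noisy discretization of the variant's latent fluorescence distribution.
Three features make naive scoring unreliable:

* **Overdispersion.** Read counts vary far more than multinomial sampling
  alone predicts, and the excess grows with sequencing depth in a roughly
  linear way. Methods that ignore this understate uncertainty and call too
  many false discoveries.
* **Unequal amplification across bins.** When bins receive different cell
  numbers, PCR amplification gives low-cell bins disproportionately many
  reads, biasing any score computed from raw read shares.
* **Low per-variant information.** With a handful of replicates per
  variant, per-variant estimates are unstable; information must be shared
  across variants without erasing real differences.

`sortscore` addresses these with a hierarchical Bayesian model whose scores
are calibrated against the screen's own negative controls — synonymous
variants, which leave the protein unchanged.

## The model

Counts are first rescaled, when a FACS sort report is available, so that
each bin's read share within a replicate matches its sorted cell
proportion (`normalize_counts()`); variants with fewer than 15 raw reads
overall are removed and a pseudocount of 0.5 is added
(`filter_and_pseudocount()`). The 15-read floor is applied to raw counts
before normalization and pseudocounting — it is a sequencing-depth
criterion, and a pseudocount should never rescue an unobserved variant.
The pseudocount value itself is a small symmetric continuity correction;
since sort normalization already makes counts real-valued, nothing is
gained by keeping them integer.

For variant $v$, replicate $r$, normalized counts
$\tilde y_{vr}$ with total $N_{vr}$:

$$\tilde y_{vr} \sim \mathrm{DirichletMultinomial}\!\left(N_{vr},\,
\phi_{vr}\, p_{vr}\right), \qquad \phi_{vr} = a_r + b_r N_{vr}$$

The concentration $\phi_{vr}$ grows linearly with depth, absorbing the
count-variance trend seen in real screens; $a_r, b_r \ge 0$ are estimated
per replicate. Since normalized counts are real-valued, the
Dirichlet-multinomial density is evaluated through `lgamma` (a continuous
extension that coincides with the usual pmf at integer counts).

Each replicate has a baseline bin-probability simplex $q_r$ — the expected
bin distribution of a wild-type-like variant — with a flat Dirichlet prior.
(A uniform prior "on each probability" only makes sense jointly on the
simplex, and the flat Dirichlet is the unique uniform distribution there.)
The baseline defines standard-normal cutoffs
$t_{r,k} = \Phi^{-1}(q_{r,1} + \dots + q_{r,k})$, and a variant's bin
probabilities are those of a unit-variance normal shifted by its effect
$\beta_v$:

$$p_{vrk} = \Phi(t_{r,k} - \beta_v) - \Phi(t_{r,k-1} - \beta_v).$$

So $\beta_v$ is a location shift in standard-normal quantile units: 0 means
wild-type-like, positive means higher fluorescence (gain of function),
negative lower (loss of function). Bin 1 is always the lowest-fluorescence
bin, in every module of this package.

Effects are shared hierarchically. Missense effects at position $p$ draw
from $\mathrm{Normal}(\theta_p, \sigma_p^2)$, shrinking noisy variants
toward their position's mean. Synonymous variants deliberately bypass this
hierarchy — each synonymous mutation $s$ gets its own fixed mean,
$\beta_s \sim \mathrm{Normal}(\theta_s, \sigma_0^2)$, with a single shared
variance — so that the negative-control group is not itself shrunk toward
any signal. Note the synonymous rows enter the same shift likelihood as
everyone else: if they were pinned exactly to $q_r$, their posterior
effects would never leave the prior and the calibration below would be
vacuous. Priors: $\theta_p, \theta_s \sim \mathrm{Normal}(0,1)$;
$\sigma_p, \sigma_0 \sim \mathrm{InvGamma}(1,1)$; $a_r \in [0, 500]$ and
$b_r \in [0, 10]$ flat, with $\phi$ floored at $10^{-6}$ (the
Dirichlet-multinomial needs a strictly positive concentration). With
`use_position_hierarchy = FALSE`, missense effects instead share a single
$\mathrm{Normal}(0, \sigma_\beta^2)$ with
$\sigma_\beta \sim \mathrm{InvGamma}(1,1)$.

### Sampling

The joint posterior is explored by MCMC with `rjags` (Gibbs/slice
sampling). The Dirichlet-multinomial with real-valued counts is not a JAGS
built-in, so its log-density kernel is encoded with the standard
zeros-trick Poisson device; the probit link and `loggam` express the
quantile-shift likelihood exactly as written above. Defaults are 4 chains
of 1000 warmup + 1000 retained draws; every fit is reproducible from its
seed, and R-hat plus effective sample sizes are reported (a slice sampler
has no divergence count). Raw $\beta_v$ draws can share a slowly-mixing
common offset with $q_r$ — the model is only identified up to that shift
through the synonymous priors — which inflates R-hat on $\beta$ without
harming the *corrected* scores, because the offset cancels in the
correction described next.

### Calibration and discovery

For each retained draw $d$ and variant $v$, a synonymous variant $s_{vd}$
is drawn uniformly (independently per variant and draw, with replacement)
and its same-draw effect is subtracted:

$$\beta^*_{vd} = \beta_{vd} - \beta_{s_{vd},d}.$$

The corrected score $\hat\beta_v$ is the mean of $\beta^*_{vd}$, its
uncertainty $\hat\sigma_v$ the SD. This propagates the spread *between*
synonymous mutations — the floor of biologically meaningless variation —
into every variant's uncertainty, and removes any shared offset between
effects and baseline. Discoveries are called by the local false sign rate,

$$\mathrm{lfsr}_v = \min\Big(\tfrac1D\sum_d 1[\beta^*_{vd} \le 0],\;
\tfrac1D \sum_d 1[\beta^*_{vd} \ge 0]\Big),$$

at a default threshold of 0.05. Draws exactly at zero count on both sides
(conservative), and values are capped at 0.5. The sign of a discovery is
GOF for positive $\hat\beta_v$, LOF for negative.

## Baseline scorers

Two standard approaches are included for comparison. The **weighted
mean-bin** score averages bin indices weighted by counts,
$w_{vr} = \sum_k (k/K)\, y_{vrk} / \sum_k y_{vrk}$, averages over
replicates, and centers on the synonymous mean. The **ML log-normal**
score fits each variant's latent fluorescence as a log-normal by
maximizing the binned likelihood against the raw FACS gate positions
(Nelder-Mead over $(\mu, \log\sigma)$, multi-start from the mean-bin
implied quantiles; raw counts are the likelihood weights). Both are
centered on the synonymous mean and call discoveries from a normal fit to
the synonymous score distribution — a 2-SD cutoff, i.e. two-sided
$p < 0.05$, with no multiple-testing correction, matching field practice.
Variants with all mass in a single unbounded tail bin have no identifiable
location and are flagged rather than scored.

## The simulator

`simulate_dataset()` generates a full experiment so that scoring methods
can be compared against known truth:

1. **Effect pattern.** A binary P×V matrix marks which variant slots carry
   effects; synonymous slots never do. `build_effect_pattern()` toggles
   entries uniformly at random to hit a target effect proportion exactly.
2. **Ground truth.** Each effect position draws a mean from a
   two-component mixture — small (wild-type-like) with probability
   `p_small`, else large — truncated by rejection (not clipping, to avoid
   boundary atoms) to 2 SDs of its component; slot effects scatter around
   the position mean with SD `sigma_p`.
3. **Sort.** Each variant contributes `m = 200` cells drawn from
   `LogNormal(mu0 + beta_v + b_r, tau)`; replicate shifts `b_r` are R
   equidistant steps in `[-B, B]`. Gates sit at equally spaced quantiles
   of the pooled fluorescence, optionally displaced by a log-scale gate
   offset; sorted cell fractions define the true bin probabilities.
4. **Reads.** Per (variant, replicate), a read total is resampled from the
   seed data (or a negative binomial with mean `L/(n_variants * R)` and
   size 10 in synthetic mode — depth variation typical of pooled
   libraries), and bin reads are Dirichlet-multinomial with concentration
   `eta_v * p0`, where `eta` follows a linear trend in mean depth
   estimated from synonymous variants by Brent's method on (0, 1000) plus
   OLS. Alternatively, bin-level overdispersion `psi_k` redistributes a
   fixed `L/(K*R)` reads per bin across variants, stressing
   PCR-amplification bias.

When seeded from data (`config_from_data()`), the mixture, effect pattern
(mean-bin discoveries at the 2-SD cutoff), wild-type log-normal, eta
trend, and read pool are all estimated from the input counts. The
"bivariate" mixture fit is implemented as a two-component univariate
Gaussian mixture (scores are one-dimensional); the small-effect mode is
the component holding more synonymous variants, ties broken by smaller
absolute mean. Synthetic-mode defaults (`mu0 = 5`, `tau = 0.5`,
`p_small = 0.7`, `mu_small = 0`, `sigma_small = 0.15`, `mu_large = -1.5`,
`sigma_large = 0.5`, `sigma_p = 0.3`, `eta = 1 + 0.02 N`, `L = 10^6`,
`m = 200`) are fixture choices describing a plausible mid-size abundance
screen, not estimates from any particular dataset.

What the simulator does *not* emulate: barcode collisions and mapping
error, cell-cycle or expression heterogeneity beyond the log-normal,
gate spillover, and replicate-specific gate drift beyond a location
shift. Passing benchmarks here shows correct behavior under the stated
generative assumptions, not under every real-data pathology.

## Benchmarking

`fdr_sensitivity()` uses the conventions FDR = FP / max(1, discoveries)
(an empty discovery set has FDR 0 — the 0/0 case must be defined somehow
and this is the conservative choice for comparing methods) and
sensitivity = TP / max(1, true effects). `run_benchmark_grid()` repeats
each configuration (default 10 times) with distinct derived seeds and
reports means with standard errors (SD/√n); a method failing on a repeat
is recorded as `NA`, never dropped. Synonymous variants are excluded from
the evaluation set — they are the controls. `synonymous_masking_fdr()`
estimates empirical FDR on real data without ground truth: 20% of
synonymous variants are relabeled missense (keeping their positions, and
hence position-level shrinkage), the data are rescored with the remainder
as controls, and the fraction of masked variants called significant is
the FDR estimate, averaged over 10 masks.

## Numerical and design notes

* `quantile_cutoffs()` rejects zero bin probabilities (infinite cutoffs);
  the model's Dirichlet prior keeps $q_r$ interior.
* Totals $N_{vr}$ are kept real-valued after normalization; rounding
  would discard exactly the correction normalization applies.
* Bias-correction resampling is with replacement, independently per
  (variant, draw); with `S` synonymous controls the correction adds their
  between-mutation variance to every score, which is the point.
* The eta trend intercept/slope orientation is named explicitly
  (`eta_intercept`, `eta_slope`) to avoid the ambiguity of one-letter
  conventions; the model's trend `phi = a_r + b_r N` names `a_r` the
  intercept likewise.
* Reads per bin in the bin-overdispersion route are `L/(K*R)` so a
  simulated experiment totals `L` reads regardless of replicate count.
* Test and benchmark problem sizes in this package (e.g. P = 15–20
  positions, 5 variant slots per position, 2×500+500 or 1×400+400 MCMC
  draws) are chosen so the full suite exercises every stage end-to-end at
  desk scale; the same code runs unchanged at screen scale with the
  defaults (P = 100, 4×1000+1000).

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(P = 20, variants_per_position = 5,
                         syn_per_position = 1, R = 3, K = 4, m = 200,
                         L = 1e6, effect_proportion = 0.5)
sim <- simulate_dataset(cfg, seed = 1)
kept <- filter_and_pseudocount(sim$counts)
effects <- score_variants(kept, seed = 2, chains = 2,
                          warmup = 500, samples = 500)
head(effects[order(effects$lfsr), ])
table(effects$sign, effects$class)

# compare with the mean-bin baseline against ground truth
bm <- run_benchmark_grid(cfg, methods = c("bayes", "meanbin"),
                         n_repeats = 10, seed = 3,
                         scorer_args = list(chains = 1, warmup = 400,
                                            samples = 400))
bm$summary
```

## Limitations

* Scoring requires at least two synonymous variants; screens without
  negative controls (or scored against a known wild-type baseline
  proportion) are out of scope.
* The slice sampler is slower per effective draw than gradient-based
  samplers on strongly correlated posteriors; for very large screens,
  fitting positions in blocks or reducing chains is advisable.
* lfsr is reported in [0, 0.5]; it measures sign confidence, not effect
  magnitude — use `beta_hat` with `sigma_hat` for magnitudes.
* Enrich2 and other external scorers are not reimplemented; their output
  can be benchmarked by wrapping a reader as a scorer function.
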
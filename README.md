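# samplefence

Simulation and hierarchical Bayesian analysis of how people sample from
known histograms when estimating a hidden mean.

## The problem

In many information-search settings — online product reviews, lotteries,
star-rating interfaces — people can see the *shape* of an outcome
distribution (a five-bin histogram with per-bin probabilities) but not the
*values* behind it, and must actively sample to estimate the true mean. The
efficient, unbiased strategy in this environment is **proportional
stratified sampling**: allocate draws to bins in proportion to their
probabilities `g`. Human samplers instead over-sample rare bins,
which biases the *experienced mean* (the average of what they drew) away
from the true mean in skewed environments, and only partially correct for
this when reporting estimates.

`samplefence` implements this whole study pipeline as reusable, testable
code:

- **Task environment** — binned, scaled beta stimuli: negatively skewed
  Beta(3, 1), positively skewed Beta(1, 3), and uniform Beta(1, 1) on
  \[0, 1\], cut into 5 equal-width bins, scaled per trial by a multiplier
  uniform on \[50, 100\]. Exact bin probabilities, within-bin moments and
  truncated-beta draws.
- **Sampling agents** — a synthetic-data generator with stratified
  (largest-remainder), multinomial, and **cognitive-fencing mixture**
  allocation policies. The fencing model attributes allocation behavior to
  a mixture of the objective histogram and a uniform, range-covering
  component:

  `f(x) = (1 − w) · g(x) + w · u(x)`,  `w ∈ [0, 1]`.

  Estimates are generated as partially bias-corrected experienced means
  with Gaussian noise.
- **Bias statistics** — preregistered exclusion rules; per-trial sampling
  bias (experienced − true), estimation deviation (estimate − true) and
  estimation adjustment (experienced − estimate); pooled exact binomial
  tests of allocation shares with Clopper–Pearson intervals;
  participant-clustered bootstrap condition summaries;
  stratified-vs-SRS efficiency; the linear incentive-loss rule.
- **Hierarchical inference** — participant-level weights
  `w_i ~ TruncNormal(μw, σw, [0, 1])` with weak hyperpriors, fitted by an
  adaptive Metropolis-within-Gibbs sampler (4 chains × 2000 iterations,
  1000 warmup by default) with split-Rhat/ESS diagnostics, a
  parameter-recovery harness, and the follow-up regression of
  |estimation adjustment| on `w`.

## Worked example

```r
library(samplefence)

ex   <- simulate_experiment(experiment_design(n_participants = 145),
                            population_params(mu_w = 0.5, sigma_w = 0.2),
                            seed = 42)
excl <- apply_exclusions(ex$trials)
summ <- condition_summaries(excl$trials, n_boot = 2000, seed = 42)
summ[, c("condition", "budget", "sampling_bias", "estimation_adjustment")]
#>   condition budget sampling_bias estimation_adjustment
#> 1  negative     10      -0.11024              -0.04951
#> 2  negative     20      -0.11643              -0.05954
#> 3  positive     10       0.11280               0.05702
#> 4  positive     20       0.11477               0.05047
#> 5   uniform     10       0.00555              -0.00015
#> 6   uniform     20       0.00203               0.00334

pooled_bin_test(excl$trials, "negative", 1, bin_probabilities("negative")[1])
#> <proportion_test> negative bin 1: 889/8720 = 0.102 vs p0 = 0.008
#>   p = 0, 95% CI [0.096, 0.108]

fit_hierarchical(excl$trials, mcmc_config(seed = 42))
#> <fence_fit> 145 participants, 4 chains x 1000 draws
#>  parameter      mean    ci_low   ci_high     rhat      ess
#>       mu_w 0.4866645 0.4493118 0.5246394 1.004095 673.6962
#>    sigma_w 0.2024929 0.1671148 0.2518106 1.018673 287.2542
```

Reading the output: agents simulated with a population mixture weight of
0.5 allocate ~10% of their draws to the rarest bin of the negatively
skewed histogram — an order of magnitude above the 0.8% a stratified
sampler would spend there — which drags their experienced means ~0.11
below the true mean (negative skew) and ~0.11 above it (positive skew),
while the uniform condition stays unbiased. Their reported estimates
recover about half of that bias (the `estimation_adjustment` column), and
the hierarchical fit recovers the generating population weight
(posterior mean μw ≈ 0.49, 95% CrI \[0.45, 0.52\]).

A thin command-line wrapper over the same functions is installed at
`inst/cli/samplefence.R`:

```sh
Rscript inst/cli/samplefence.R simulate n_participants=145 seed=1 out=trials.csv
Rscript inst/cli/samplefence.R stats trials=trials.csv out_dir=results
Rscript inst/cli/samplefence.R fit trials=trials.csv out=posterior.csv
```

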
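---
title: "The cognitive-fencing model of biased sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cognitive-fencing model of biased sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samplefence)
```

## The task environment

The environment models a rating-style information-search task. Each trial
presents a five-bin histogram over a hidden value scale. The underlying
value distribution is a beta on the normalized support $[0,1]$ — negatively
skewed $\mathrm{Beta}(3,1)$, positively skewed $\mathrm{Beta}(1,3)$, or
uniform $\mathrm{Beta}(1,1)$ — scaled by a per-trial multiplier drawn
uniformly from $[50,100]$ so that the displayed "positivity scores" range
over roughly $0$–$100$ while the true range stays masked across trials.

The support is cut into five equal-width bins with edges
$(0, 0.2, 0.4, 0.6, 0.8, 1)$; bins are half-open $[a, b)$ except the last,
which is closed at $1$ (the standard histogram convention — for a
continuous distribution the choice carries zero probability mass). The bin
probabilities $g_k = F(b_k) - F(a_k)$ come from the exact beta CDF; for the
negatively skewed shape, $F(x) = x^3$, giving
$g = (0.008, 0.056, 0.152, 0.296, 0.488)$. Within-bin conditional means and
variances are exact beta integrals computed through shifted-shape beta CDFs
(the integral of $x^j$ over a bin of $\mathrm{Beta}(a,b)$ is a
$\mathrm{Beta}(a+j,b)$ CDF difference times a ratio of normalizing
constants), so the law of total expectation $\sum_k g_k m_k = \mu$ holds to
numerical precision. Sampling a bin draws from the bin-truncated beta by
inverse-CDF transform.

All internal computation lives on the normalized scale; the multiplier is
applied only when values are displayed or drawn. Biases of magnitude
$\sim 0.1$ are therefore directly comparable across trials with different
multipliers.

## Sampling policies

Three allocation policies distribute a fixed budget $N \in \{10, 20\}$ over
the bins:

* **Stratified-deterministic** — proportional quotas $N g_k$ rounded by the
  largest-remainder (Hamilton) method, ties broken toward lower bin index.
  This is the efficient, unbiased benchmark. The integerization rule is a
  design choice; largest-remainder minimizes the total absolute deviation
  from the quotas among integer allocations (verified exhaustively in the
  tests for small budgets).
* **Stratified-random** — multinomial with probabilities $g$; the null
  model behind the pooled binomial tests.
* **Fencing mixture** — multinomial with probabilities
  $f_k(w) = (1-w)\,g_k + w/5$. The weight $w$ captures how much of the
  allocation reflects a uniform, range-covering tendency ("cognitive
  fencing") rather than the objective histogram. At $w = 0.51$ the mixture
  spends $f_1 = 0.106$ of the budget on the rarest bin of the negatively
  skewed histogram, versus the stratified benchmark of $g_1 = 0.008$.

In the uniform condition $f(w) = g$ for every $w$: mixture agents are
indistinguishable from stratified-random there, which is why (a) simulated
experienced means are unbiased in that condition and (b) uniform trials
carry no likelihood information about $w$.

## The synthetic-data generator

`simulate_experiment()` emulates the full study structure: 145 participants
by default, a between-subject budget of 10 or 20 samples with a 50/50
split, three within-subject shape
conditions presented in randomized block order with four trials each, and
per-trial multipliers independent across trials. Participant weights come
from a $\mathrm{Normal}(\mu_w, \sigma_w)$ truncated to $[0,1]$ — a mixture
proportion needs a bounded support, and truncation is the minimal way to
impose it while keeping the stated population form.

Real participants report estimates; simulated agents need a generative
stand-in. We use a linear partial-correction model:
$$\hat{m} = \bar{x} - \kappa\, \mathbb{E}[\text{bias}(w)] + \varepsilon,
  \qquad \varepsilon \sim \mathrm{Normal}(0, \sigma_e),$$
clamped to $[0,1]$ and rescaled by the multiplier, where
$\mathbb{E}[\text{bias}(w)] = \sum_k f_k(w) m_k - \mu$ is the analytic
expected bias of the agent's own policy. The defaults $\kappa = 0.5$,
$\sigma_e = 0.05$ are the package's choice of a realistic regime: a
half-corrected bias reproduces the qualitative empirical pattern in which
estimates sit between the experienced mean and the true mean (adjustments
of roughly $\mp 0.05$ against sampling biases of roughly $\mp 0.11$ at
$\mu_w = 0.5$), and a noise SD of 5 scale points is a plausible reporting
error for a 0–100 response. $\kappa$ and $\sigma_e$ are deliberately simple
plumbing — the scientific content is in the allocation model, and the
recovery results do not depend on the estimate channel (the likelihood uses
counts only).

What the generator does *not* emulate: within-trial sequential dynamics
(only final counts are modeled), attention or motivated-search processes,
any deterministic drive to cover all five bins (real samplers nearly always
touch every bin at least once; the multinomial mixture reproduces this only
on average), participant dropout, or response styles such as rounding
estimates to multiples of 5. Passing tests therefore certify the pipeline's
statistical machinery on data whose generating process is known, not that
the fencing model is the true account of human allocation.

## Statistics and exclusion rules

The preregistered exclusions are applied in order: trials in which only one
bin was sampled are dropped; participants whose reported estimate is
identical on every trial are dropped; participants with two or more
excluded trials are dropped entirely.

Three per-trial quantities (normalized scale) carry the analysis:
sampling bias $=\bar{x} - \mu$, estimation deviation $=\hat{m} - \mu$, and
estimation adjustment $=\bar{x} - \hat{m}$, which satisfy
$\text{bias} = \text{deviation} + \text{adjustment}$ identically. The
adjustment sign convention (experienced minus estimate) makes adjustments
take the same sign as the bias being corrected: negative in the negative-skew
condition, positive in the positive-skew condition.

Allocation shares are tested by pooling all samples within a condition
across trials and participants and comparing the pooled count for a bin
against the stratified expectation $g_k$ with an exact binomial test. The
two-sided p-value doubles the smaller exact tail (capped at 1) — a
convention chosen for its transparency and exact brute-force verifiability —
and the 95% interval is Clopper–Pearson. Pooling is deliberate: per-sample
pooling is what makes condition-level shares estimable with tight intervals,
and the package does not model per-participant test heterogeneity.

Condition-level means of the three statistics are summarized with a
participant-clustered percentile bootstrap (resample participants with
replacement, 2000 resamples by default) rather than a parametric mixed
model: the intervals are descriptive companions to the simulation results,
make no distributional assumptions, and respect the repeated-measures
structure.

Stratified efficiency uses the variance decomposition
$\mathrm{Var} = \sum_k g_k s^2_k + \sum_k g_k (m_k - \mu)^2$: proportional
stratification retains only the within-bin component, so its variance ratio
against simple random sampling is $\le 1$ in every condition. The incentive
loss of relying on a biased mean is modeled as linear in the mean absolute
deviation: a deviation of 13.5% of the scale forfeits £1.08 of an £8 bonus.

## Hierarchical inference of the mixture weight

The observation model treats each trial's counts as
$\mathrm{Multinomial}(N, f(w_i))$ — the minimal exchangeable likelihood for
final allocation counts. Uniform-condition trials are excluded from the
likelihood (uninformative, as above) and both budget arms are pooled into
one fit, giving a single population estimate. The hierarchy is

$$w_i \sim \mathrm{TruncNormal}(\mu_w, \sigma_w, [0,1]), \qquad
  \mu_w \sim \mathrm{TruncNormal}(0.5, 1, [0,1]), \qquad
  \sigma_w \sim \mathrm{HalfNormal}(1),$$

with weakly informative hyperpriors that keep the posterior proper at the
boundaries ($\sigma_w \to 0$, $\mu_w \to \{0,1\}$) without pulling the
population mean anywhere in particular.

The sampler is an adaptive random-walk Metropolis-within-Gibbs on
transformed parameters: $\mathrm{logit}(w_i)$, $\mathrm{logit}(\mu_w)$,
$\log(\sigma_w)$, with the usual Jacobian terms. The participant weights
are conditionally independent given the hyperparameters, so all $w_i$ are
proposed and accepted/rejected componentwise in one vectorized step;
per-participant likelihoods reduce to inner products of condition-summed
counts with $\log f(w)$, which is what makes a 145-participant fit run in a
few seconds. Proposal scales adapt during warmup toward the 0.44 acceptance
rate that is optimal for scalar random-walk updates, with a
$\min(0.25, 1/\sqrt{t})$ adaptation schedule (diminishing, so the
post-warmup chain is a valid fixed-kernel sampler). Defaults are four
chains of 2000 iterations with 1000 warmup. Convergence is monitored with
split-Rhat and an autocorrelation-based effective sample size; fits with
split-Rhat above 1.05 on a population parameter raise a warning and are
flagged in the returned object, never silently accepted.

Correctness is established against implementation-independent oracles: the
multinomial likelihood against direct lgamma evaluation and `dmultinom`;
the joint log-posterior against term-by-term recomputation; and the
posterior mean of $w$ on a tiny instance (one participant, one trial)
against deterministic grid integration of the full
$(w, \mu_w, \sigma_w)$ posterior, which agrees within 0.02.

`recovery_study()` closes the loop: simulate at known $(\mu_w, \sigma_w)$,
fit, and record bias, RMSE and 95%-interval coverage of the truth. At the
study-scale design (145 participants, 8 skewed trials each) the posterior
mean of $\mu_w$ at $(\mu_w, \sigma_w) = (0.5, 0.2)$ is recovered with
absolute bias below 0.05 and near-nominal coverage, and degenerate
populations at $\mu_w \in \{0, 1\}$ are recovered to the correct boundary
(posterior means below 0.1 / above 0.9). Boundary fits mix poorly in
$\sigma_w$ (its posterior piles up near 0) and are expected to trip the
convergence warning while still locating $\mu_w$ correctly.

The follow-up regression models $|{\text{adjustment}}|$ on $w$, condition,
and their interaction with participant-clustered bootstrap intervals. Under
the generator this is positively identified exactly when $\kappa > 0$:
agents that fence more incur more expected bias, and correct more.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite are chosen to keep the full run in a few
  minutes: Monte Carlo checks use $10^4$–$10^5$ replicates with 3–4
  standard-error tolerances; the recovery study uses 10 replications at the
  study-scale design.
* Master seeds: every simulation entry point takes a `seed` and derives all
  randomness from it; chain seeds are `seed * 1000 + chain`. Identical
  seeds reproduce byte-identical trial CSVs.
* Degenerate inputs: empty trial tables yield empty outputs with zeroed
  exclusion reports; uniform-only data make `fence_data()` fail loudly
  ("no informative trials"); a condition×budget cell with no trials is
  omitted from summaries with a warning; $\sigma_w \le 0$ has zero
  posterior density.
* Trial CSVs store normalized draw values at full double precision
  (`%.17g`), so write/read round-trips are exact for integers and within
  $10^{-12}$ for reals.

## Known limitations

The fitted $\sigma_w$ is only as identified as the per-participant trial
count allows; with 8 skewed trials of 10–20 samples the likelihood per
participant is modest and the hierarchy does real work. The estimate model
is intentionally minimal and should not be read as a cognitive theory of
reporting. The binomial tests pool samples and therefore inherit the usual
caveat that within-participant dependence is not reflected in their
intervals — the clustered bootstrap summaries are the dependence-aware
companion.
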
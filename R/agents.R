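#' Cognitive-fencing mixture allocation probabilities
#'
#' The fencing account models a participant's allocation distribution over
#' bins as a mixture of the objective stimulus histogram `g` and a uniform
#' histogram `u` that captures the tendency to cover the full range of
#' values: `f = (1 - w) * g + w * u`. The weight `w` in \[0, 1\] is the share
#' of behavior attributable to the range-covering component.
#'
#' @param g Probability vector over bins (sums to 1).
#' @param w Mixture weight in \[0, 1\].
#' @return Probability vector of the same length as `g`.
#' @examples
#' mixture_probs(bin_probabilities("negative"), w = 0.51)[1]  # ~0.106
#' @export
mixture_probs <- function(g, w) {
  if (length(w) != 1L || !is.finite(w) || w < 0 || w > 1) {
    stop("mixture weight `w` must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(abs(sum(g) - 1) < 1e-8, all(g >= 0))
  (1 - w) * g + w / length(g)
}

#' Deterministic proportional stratified allocation
#'
#' Allocates an integer sample budget over bins proportionally to the bin
#' probabilities, using largest-remainder (Hamilton) rounding: each bin gets
#' the floor of its quota `budget * g_k`, and the remaining samples go to the
#' bins with the largest fractional remainders. Ties are broken by lower bin
#' index. This is the efficient, unbiased baseline policy against which
#' observed allocation is compared.
#'
#' @inheritParams mixture_probs
#' @param budget Total number of samples (integer >= 1).
#' @return Integer vector of counts summing to `budget`.
#' @examples
#' stratified_allocation(bin_probabilities("negative"), 10)  # 0 1 1 3 5
#' @export
stratified_allocation <- function(g, budget) {
  stopifnot(length(budget) == 1L, budget >= 1, budget == round(budget))
  quota <- budget * g / sum(g)
  counts <- floor(quota)
  short <- round(budget - sum(counts))
  if (short > 0) {
    rem <- quota - counts
    take <- order(-rem, seq_along(g))[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Allocate a sampling budget under a named policy
#'
#' @inheritParams stratified_allocation
#' @param policy `"stratified-deterministic"` (largest-remainder proportional
#'   allocation), `"stratified-random"` (multinomial with probabilities `g`,
#'   the null model of the binomial tests), or `"mixture"` (multinomial with
#'   fencing-mixture probabilities `f(w)`).
#' @param w Mixture weight, required for `policy = "mixture"`.
#' @return Integer vector of counts summing to `budget`.
#' @export
sample_allocation <- function(policy = c("stratified-deterministic",
                                         "stratified-random", "mixture"),
                              g, budget, w = NULL) {
  policy <- match.arg(policy)
  switch(policy,
    "stratified-deterministic" = stratified_allocation(g, budget),
    "stratified-random" = as.integer(stats::rmultinom(1, budget, g)),
    "mixture" = {
      if (is.null(w)) stop("`w` is required for the mixture policy", call. = FALSE)
      as.integer(stats::rmultinom(1, budget, mixture_probs(g, w)))
    }
  )
}

#' Expected experienced-mean bias of the mixture policy
#'
#' Under allocation probabilities `f(w)` the expected experienced mean is
#' `sum(f_k * m_k)`; its deviation from the true mean `mu` is the analytic
#' sampling bias an agent with weight `w` incurs in expectation. Zero in the
#' uniform condition for every `w` (there `f = g = u`).
#'
#' @inheritParams true_mean
#' @param w Mixture weight in \[0, 1\].
#' @return Expected sampling bias on the normalized scale.
#' @export
expected_bias <- function(dist, w) {
  stopifnot(inherits(dist, "binned_dist"))
  f <- mixture_probs(dist$g, w)
  sum(f * dist$m) - dist$mu
}

#' Agent parameters
#'
#' A simulated participant is described by the mixture weight `w`, a
#' bias-adjustment factor `kappa` (how much of their own expected sampling
#' bias they correct when reporting an estimate), and the estimate noise
#' standard deviation `sigma_e` on the normalized scale. The estimate model
#' is a simple generative stand-in for participants' reports; the fencing
#' mixture governs allocation only.
#'
#' @param w Mixture weight in \[0, 1\].
#' @param kappa Adjustment factor in \[0, 1\].
#' @param sigma_e Estimate noise SD (normalized units, >= 0).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(w, kappa = 0.5, sigma_e = 0.05) {
  stopifnot(w >= 0, w <= 1, kappa >= 0, kappa <= 1, sigma_e >= 0)
  structure(list(w = w, kappa = kappa, sigma_e = sigma_e),
            class = "agent_params")
}

#' Generate a participant's estimate for one trial
#'
#' The agent reports the experienced mean of the trial, partially corrected
#' for the analytic expected bias of its own allocation policy:
#' `estimate = experienced_mean - kappa * expected_bias(w) + noise`, clamped
#' to \[0, 1\] and returned on the positivity-score scale.
#'
#' @param values Normalized drawn values of the trial (length >= 1).
#' @param agent An [agent_params()] object.
#' @inheritParams true_mean
#' @return Estimate on the raw (positivity-score) scale.
#' @export
generate_estimate <- function(values, agent, dist) {
  stopifnot(inherits(agent, "agent_params"), inherits(dist, "binned_dist"))
  if (length(values) < 1L) stop("trial has no draws", call. = FALSE)
  est <- mean(values) - agent$kappa * expected_bias(dist, agent$w) +
    stats::rnorm(1, 0, agent$sigma_e)
  min(max(est, 0), 1) * dist$multiplier
}

#' Experiment design
#'
#' @param n_participants Number of simulated participants.
#' @param budget_split Fraction assigned to the 10-sample arm (default 0.5).
#' @param trials_per_condition Trials per shape condition (default 4).
#' @param budgets The two between-subject sample budgets (default `c(10, 20)`).
#' @param n_bins Bins per histogram (default 5).
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(n_participants = 145L, budget_split = 0.5,
                              trials_per_condition = 4L,
                              budgets = c(10L, 20L), n_bins = 5L) {
  stopifnot(n_participants >= 1, trials_per_condition >= 1,
            budget_split >= 0, budget_split <= 1, length(budgets) == 2L)
  structure(
    list(n_participants = as.integer(n_participants),
         budget_split = budget_split,
         trials_per_condition = as.integer(trials_per_condition),
         budgets = as.integer(budgets), n_bins = as.integer(n_bins)),
    class = "experiment_design"
  )
}

#' Population distribution of the mixture weight
#'
#' Participant-level weights are drawn from a Normal(`mu_w`, `sigma_w`)
#' truncated to \[0, 1\] — the weight is a mixture proportion, so the
#' population distribution must live on the unit interval. `sigma_w = 0` is
#' accepted as the degenerate population with every `w = mu_w`.
#'
#' @param mu_w Population mean of `w`.
#' @param sigma_w Population SD of `w` (>= 0).
#' @return A list of class `population_params`.
#' @export
population_params <- function(mu_w, sigma_w) {
  stopifnot(sigma_w >= 0)
  structure(list(mu_w = mu_w, sigma_w = sigma_w), class = "population_params")
}

rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(min(max(mean, 0), 1), n))
  plo <- stats::pnorm(0, mean, sd)
  phi <- stats::pnorm(1, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate a full sampling experiment
#'
#' Generates a complete synthetic experiment with the study's design
#' structure: each participant is assigned one sample budget (the first
#' `floor(budget_split * n)` participants after a seeded shuffle get the
#' smaller budget), receives one mixture weight `w` drawn from the truncated
#' normal population, and completes `trials_per_condition` trials in each of
#' the three shape conditions, presented in a randomized block order. Each
#' trial gets an independent scale multiplier uniform on \[50, 100\], a
#' multinomial allocation of the budget under the agent's fencing-mixture
#' probabilities, truncated-beta draws from the sampled bins, and a reported
#' estimate from the partial-correction model.
#'
#' @param design An [experiment_design()].
#' @param pop A [population_params()].
#' @param kappa,sigma_e Estimate-model parameters shared by all agents.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `fence_experiment` with elements `trials` (tibble,
#'   one row per trial; bin counts in columns `n1..n5`, draws as a list-column
#'   of tibbles), `agents` (tibble of true per-participant parameters),
#'   `design`, and `seed`.
#' @examples
#' ex <- simulate_experiment(experiment_design(n_participants = 4),
#'                           population_params(0.5, 0.2), seed = 1)
#' nrow(ex$trials)  # 4 participants x 12 trials
#' @export
simulate_experiment <- function(design = experiment_design(),
                                pop = population_params(0.5, 0.2),
                                kappa = 0.5, sigma_e = 0.05, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(pop, "population_params"))
  set.seed(seed)
  n <- design$n_participants
  arm_order <- sample.int(n)
  budget <- integer(n)
  n_small <- floor(design$budget_split * n)
  budget[arm_order[seq_len(n_small)]] <- design$budgets[1L]
  budget[budget == 0L] <- design$budgets[2L]
  w <- rtruncnorm01(n, pop$mu_w, pop$sigma_w)

  conds <- shape_conditions()
  tpc <- design$trials_per_condition
  rows <- vector("list", n * 3L * tpc)
  r <- 0L
  for (i in seq_len(n)) {
    agent <- agent_params(w[i], kappa, sigma_e)
    block <- sample(conds)
    t_idx <- 0L
    for (cond in block) {
      for (j in seq_len(tpc)) {
        t_idx <- t_idx + 1L
        dist <- make_trial_stimulus(cond, design$n_bins)
        counts <- sample_allocation("mixture", dist$g, budget[i], w = w[i])
        draws <- do.call(rbind, lapply(which(counts > 0L), function(k) {
          draw_from_bin(dist, k, n = counts[k])
        }))
        est <- generate_estimate(draws$value, agent, dist)
        r <- r + 1L
        rows[[r]] <- tibble::tibble(
          participant_id = i, trial_index = t_idx, condition = cond,
          budget = budget[i], multiplier = dist$multiplier,
          counts = list(counts), draws = list(draws), estimate_raw = est
        )
      }
    }
  }
  trials <- dplyr::bind_rows(rows)
  cmat <- do.call(rbind, trials$counts)
  colnames(cmat) <- paste0("n", seq_len(design$n_bins))
  trials <- dplyr::bind_cols(
    trials[setdiff(names(trials), "counts")],
    tibble::as_tibble(cmat)
  )
  trials <- trials[, c("participant_id", "trial_index", "condition", "budget",
                       "multiplier", paste0("n", seq_len(design$n_bins)),
                       "estimate_raw", "draws")]
  structure(
    list(trials = trials,
         agents = tibble::tibble(participant_id = seq_len(n), budget = budget,
                                 w = w, kappa = kappa, sigma_e = sigma_e),
         design = design, seed = as.integer(seed)),
    class = "fence_experiment"
  )
}

#' @export
print.fence_experiment <- function(x, ...) {
  cat(sprintf("<fence_experiment> %d participants, %d trials, seed %d\n",
              x$design$n_participants, nrow(x$trials), x$seed))
  invisible(x)
}
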
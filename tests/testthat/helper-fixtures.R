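# hand-buildable trial rows for crafted fixtures

empty_draws <- function() {
  tibble::tibble(bin = integer(), value = numeric(), raw = numeric())
}

# one trial row with given counts; draws are placed at the midpoint of each
# sampled bin so all invariants (draw count, bin membership) hold
trial_row <- function(participant_id, trial_index, condition, counts,
                      estimate_raw = 40, multiplier = 80, budget = sum(counts)) {
  mids <- (seq_along(counts) - 0.5) / length(counts)
  bins <- rep(seq_along(counts), counts)
  draws <- tibble::tibble(bin = as.integer(bins), value = mids[bins],
                          raw = mids[bins] * multiplier)
  out <- tibble::tibble(
    participant_id = as.integer(participant_id),
    trial_index = as.integer(trial_index),
    condition = condition, budget = as.integer(budget),
    multiplier = multiplier
  )
  for (k in seq_along(counts)) out[[paste0("n", k)]] <- as.integer(counts[k])
  out$estimate_raw <- estimate_raw
  out$draws <- list(draws)
  out
}

# a well-behaved participant: n_trials two-bin trials with distinct estimates
ok_participant <- function(id, n_trials = 3, condition = "negative") {
  dplyr::bind_rows(lapply(seq_len(n_trials), function(t) {
    trial_row(id, t, condition, c(2L, 0L, 0L, 3L, 5L),
              estimate_raw = 40 + t)
  }))
}

# numerical-integration oracle for within-bin beta moments
integrate_bin_moment <- function(alpha, beta, lo, hi, power = 1) {
  mass <- stats::integrate(function(x) stats::dbeta(x, alpha, beta),
                           lo, hi, rel.tol = 1e-12)$value
  stats::integrate(function(x) x^power * stats::dbeta(x, alpha, beta),
                   lo, hi, rel.tol = 1e-12)$value / mass
}
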
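bin_cols <- function(trials) grep("^n[0-9]+$", names(trials), value = TRUE)

counts_matrix <- function(trials) {
  as.matrix(trials[, bin_cols(trials)])
}

#' Preregistered exclusion rules
#'
#' Applies, in order: (1) drop trials in which only one bin was sampled;
#' (2) drop participants who reported the same estimate on every one of their
#' trials; (3) drop participants with two or more trials excluded under rule
#' (1). Participants removed by rule (2) or (3) lose all their trials.
#'
#' @param trials Trial tibble as produced by [simulate_experiment()] or
#'   [read_trials()].
#' @return List with `trials` (filtered tibble) and `report`, a list of
#'   class `exclusion_report` tallying each rule and the retained sample.
#' @export
apply_exclusions <- function(trials) {
  if (nrow(trials) == 0L) {
    report <- structure(list(trials_one_bin = 0L, participants_constant = 0L,
                             participants_two_rounds = 0L, retained = 0L),
                        class = "exclusion_report")
    return(list(trials = trials, report = report))
  }
  cm <- counts_matrix(trials)
  one_bin <- rowSums(cm > 0L) == 1L

  by_p <- split(seq_len(nrow(trials)), trials$participant_id)
  constant <- vapply(by_p, function(idx) {
    length(unique(trials$estimate_raw[idx])) == 1L
  }, logical(1))
  two_rounds <- vapply(by_p, function(idx) sum(one_bin[idx]) >= 2L, logical(1))

  drop_p <- names(by_p)[constant | two_rounds]
  keep <- !one_bin & !(as.character(trials$participant_id) %in% drop_p)
  report <- structure(
    list(trials_one_bin = sum(one_bin),
         participants_constant = sum(constant),
         participants_two_rounds = sum(two_rounds),
         retained = length(unique(trials$participant_id[keep]))),
    class = "exclusion_report"
  )
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report>\n")
  cat("  trials excluded (one bin sampled):     ", x$trials_one_bin, "\n")
  cat("  participants excluded (constant est.): ", x$participants_constant, "\n")
  cat("  participants excluded (2+ rounds):     ", x$participants_two_rounds, "\n")
  cat("  participants retained:                 ", x$retained, "\n")
  invisible(x)
}

#' Experienced mean of a trial
#'
#' The average of the normalized values actually drawn in a trial — the
#' quantity a participant would report if they took their sample at face
#' value.
#'
#' @param values Normalized drawn values (length >= 1).
#' @return Single numeric value on the normalized scale.
#' @export
experienced_mean <- function(values) {
  if (length(values) < 1L) stop("trial has no draws", call. = FALSE)
  mean(values)
}

#' Per-trial bias statistics
#'
#' Adds to each trial row, all on the normalized \[0, 1\] scale:
#' * `experienced` — mean of the values drawn in the trial;
#' * `sampling_bias` — experienced mean minus true mean;
#' * `estimation_deviation` — reported estimate minus true mean;
#' * `estimation_adjustment` — experienced mean minus reported estimate.
#'
#' These satisfy `sampling_bias = estimation_deviation +
#' estimation_adjustment` identically. A positive adjustment means the
#' participant reported below what they saw.
#'
#' @inheritParams apply_exclusions
#' @return The input tibble with columns `experienced`, `true_mean`,
#'   `estimate`, `sampling_bias`, `estimation_deviation`,
#'   `estimation_adjustment` appended.
#' @export
trial_statistics <- function(trials) {
  mu_of <- vapply(shape_conditions(), function(cc) {
    p <- shape_params(cc); p[["alpha"]] / (p[["alpha"]] + p[["beta"]])
  }, numeric(1))
  experienced <- vapply(trials$draws, function(d) mean(d$value), numeric(1))
  truem <- unname(mu_of[trials$condition])
  est <- trials$estimate_raw / trials$multiplier
  dplyr::mutate(trials,
    experienced = experienced,
    true_mean = truem,
    estimate = est,
    sampling_bias = experienced - truem,
    estimation_deviation = est - truem,
    estimation_adjustment = experienced - est
  )
}

#' Pooled exact binomial test of a bin's allocation share
#'
#' Pools all samples across trials and participants within one shape
#' condition and tests the observed share allocated to bin `k` against a
#' null probability `p0` (typically the stratified expectation `g_k`). The
#' two-sided p-value doubles the smaller exact tail and is capped at 1; the
#' 95% interval is Clopper–Pearson.
#'
#' @inheritParams apply_exclusions
#' @param condition Shape condition to pool over.
#' @param k Bin index.
#' @param p0 Null probability in (0, 1).
#' @return A list of class `proportion_test`.
#' @export
pooled_bin_test <- function(trials, condition, k, p0) {
  stopifnot(p0 > 0, p0 < 1)
  sub <- trials[trials$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no trials in condition ", condition, call. = FALSE)
  cm <- counts_matrix(sub)
  x <- sum(cm[, k])
  n <- sum(cm)
  if (n == 0L) stop("zero pooled samples", call. = FALSE)
  p_lo <- stats::pbinom(x, n, p0)
  p_hi <- stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
  structure(
    list(bin = as.integer(k), condition = condition,
         successes = x, total = n, p0 = p0,
         proportion = x / n,
         p_value = min(1, 2 * min(p_lo, p_hi)),
         conf_low  = if (x == 0) 0 else stats::qbeta(0.025, x, n - x + 1),
         conf_high = if (x == n) 1 else stats::qbeta(0.975, x + 1, n - x)),
    class = "proportion_test"
  )
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf(
    "<proportion_test> %s bin %d: %d/%d = %.3f vs p0 = %.3f\n  p = %.3g, 95%% CI [%.3f, %.3f]\n",
    x$condition, x$bin, x$successes, x$total, x$proportion, x$p0,
    x$p_value, x$conf_low, x$conf_high))
  invisible(x)
}

#' Condition-by-budget bias summaries with cluster bootstrap intervals
#'
#' For every shape condition crossed with sample budget, computes the mean
#' sampling bias, estimation deviation, and estimation adjustment over
#' trials, with 95% percentile intervals from a participant-clustered
#' bootstrap (participants are resampled with replacement; all their trials
#' follow them). Interval estimation is descriptive, by design: no
#' parametric mixed model is fitted.
#'
#' @param trials Trial tibble that has passed [apply_exclusions()]; the
#'   statistics columns are added via [trial_statistics()] if absent.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return Tibble with one row per condition x budget cell.
#' @export
condition_summaries <- function(trials, n_boot = 2000L, seed = 1L) {
  if (!"sampling_bias" %in% names(trials)) trials <- trial_statistics(trials)
  set.seed(seed)
  stats_cols <- c("sampling_bias", "estimation_deviation",
                  "estimation_adjustment")
  cells <- unique(trials[, c("condition", "budget")])
  cells <- cells[order(match(cells$condition, shape_conditions()),
                       cells$budget), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- trials[trials$condition == cells$condition[i] &
                  trials$budget == cells$budget[i], , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no trials in cell ", cells$condition[i], " x ",
              cells$budget[i], "; omitted")
      next
    }
    M <- as.matrix(sub[, stats_cols])
    pts <- colMeans(M)
    ids <- unique(sub$participant_id)
    by_p <- split(seq_len(nrow(sub)), sub$participant_id)
    boot <- matrix(NA_real_, n_boot, 3L)
    for (b in seq_len(n_boot)) {
      take <- unlist(by_p[sample.int(length(ids), replace = TRUE)],
                     use.names = FALSE)
      boot[b, ] <- colMeans(M[take, , drop = FALSE])
    }
    ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975))
    out[[i]] <- tibble::tibble(
      condition = cells$condition[i], budget = cells$budget[i],
      n_trials = nrow(sub), n_participants = length(ids),
      sampling_bias = pts[1], sampling_bias_low = ci[1, 1],
      sampling_bias_high = ci[2, 1],
      estimation_deviation = pts[2], estimation_deviation_low = ci[1, 2],
      estimation_deviation_high = ci[2, 2],
      estimation_adjustment = pts[3], estimation_adjustment_low = ci[1, 3],
      estimation_adjustment_high = ci[2, 3]
    )
  }
  dplyr::bind_rows(out)
}

#' Efficiency of proportional stratified sampling
#'
#' Variance of the mean estimator under proportional stratified allocation
#' versus simple random sampling for one stimulus, on the normalized scale.
#' The total variance decomposes as within plus between bins,
#' `Var = sum(g_k s2_k) + sum(g_k (m_k - mu)^2)`, so the stratified variance
#' `sum(g_k s2_k) / budget` never exceeds the SRS variance `Var / budget` —
#' stratification discards the between-bin component.
#'
#' @inheritParams true_mean
#' @param budget Total number of samples.
#' @return Named list `var_stratified`, `var_srs`, `variance_ratio`.
#' @export
stratified_efficiency <- function(dist, budget) {
  stopifnot(inherits(dist, "binned_dist"), budget >= 1)
  within <- sum(dist$g * dist$s2)
  total <- within + sum(dist$g * (dist$m - dist$mu)^2)
  list(var_stratified = within / budget,
       var_srs = total / budget,
       variance_ratio = within / total)
}

#' Incentive loss implied by estimation error
#'
#' The task pays a bonus proportional to estimation accuracy; under the
#' linear rule a mean absolute deviation of `d` (as a fraction of the scale)
#' forfeits `d * max_bonus` of the bonus.
#'
#' @param mean_abs_deviation Mean absolute deviation on the normalized scale,
#'   in \[0, 1\].
#' @param max_bonus Maximum bonus (currency; the study used 8 pounds).
#' @return Expected loss in the bonus currency.
#' @examples
#' payoff_loss(0.135, 8)  # 1.08
#' @export
payoff_loss <- function(mean_abs_deviation, max_bonus = 8) {
  stopifnot(mean_abs_deviation >= 0, mean_abs_deviation <= 1, max_bonus >= 0)
  mean_abs_deviation * max_bonus
}
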
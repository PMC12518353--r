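#' Parameter-recovery study for the hierarchical fencing model
#'
#' For each (`mu_w`, `sigma_w`) cell of a grid, repeatedly simulates a full
#' experiment, applies the exclusion rules, fits the hierarchical model, and
#' records how well the posterior recovers the generating population
#' parameters: bias and RMSE of the posterior mean of `mu_w`, and the
#' fraction of replications whose 95% credible interval covers the truth.
#'
#' @param grid Data frame with columns `mu_w` and `sigma_w`, one row per
#'   cell.
#' @param design An [experiment_design()].
#' @param n_replications Replications per cell.
#' @param seed Master seed; simulation and fitting seeds derive from it.
#' @param kappa,sigma_e Estimate-model parameters passed to the simulator.
#' @param config An [mcmc_config()] template; its seed is overridden per
#'   replication.
#' @return Tibble with one row per cell: `bias_mu_w`, `rmse_mu_w`,
#'   `coverage_mu_w`, `bias_sigma_w`, `rmse_sigma_w`, `coverage_sigma_w`,
#'   and the mean posterior means.
#' @export
recovery_study <- function(grid, design = experiment_design(),
                           n_replications = 5L, seed = 1L,
                           kappa = 0.5, sigma_e = 0.05,
                           config = mcmc_config()) {
  stopifnot(nrow(grid) >= 1, all(c("mu_w", "sigma_w") %in% names(grid)))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mu_t <- grid$mu_w[i]; sig_t <- grid$sigma_w[i]
    post_mu <- post_sig <- numeric(n_replications)
    cov_mu <- cov_sig <- logical(n_replications)
    for (r in seq_len(n_replications)) {
      rep_seed <- (seed * 131L + i * 17L + r) %% .Machine$integer.max
      ex <- simulate_experiment(design, population_params(mu_t, sig_t),
                                kappa = kappa, sigma_e = sigma_e,
                                seed = rep_seed)
      kept <- apply_exclusions(ex$trials)$trials
      cfg <- mcmc_config(config$n_chains, config$n_iterations,
                         config$n_warmup, seed = rep_seed)
      fit <- fit_hierarchical(kept, cfg)
      s <- fit$summary
      mu_row <- s[s$parameter == "mu_w", ]
      sig_row <- s[s$parameter == "sigma_w", ]
      post_mu[r] <- mu_row$mean
      post_sig[r] <- sig_row$mean
      cov_mu[r] <- mu_row$ci_low <= mu_t && mu_t <= mu_row$ci_high
      cov_sig[r] <- sig_row$ci_low <= sig_t && sig_t <= sig_row$ci_high
    }
    out[[i]] <- tibble::tibble(
      mu_w = mu_t, sigma_w = sig_t, n_replications = n_replications,
      mean_post_mu_w = mean(post_mu),
      bias_mu_w = mean(post_mu) - mu_t,
      rmse_mu_w = sqrt(mean((post_mu - mu_t)^2)),
      coverage_mu_w = mean(cov_mu),
      mean_post_sigma_w = mean(post_sig),
      bias_sigma_w = mean(post_sig) - sig_t,
      rmse_sigma_w = sqrt(mean((post_sig - sig_t)^2)),
      coverage_sigma_w = mean(cov_sig)
    )
  }
  dplyr::bind_rows(out)
}

#' Regression of absolute estimation adjustment on the mixture weight
#'
#' Tests whether the degree to which participants correct their estimates
#' away from the experienced mean tracks their fencing weight: linear model
#' of `|estimation_adjustment|` on `w`, shape-condition indicators, and
#' their interaction, with 95% percentile intervals from a
#' participant-clustered bootstrap. With a single condition in the data the
#' model reduces to `|adjustment| ~ w` with a warning.
#'
#' @param trials Trial tibble with statistics columns (see
#'   [trial_statistics()]); they are added if absent.
#' @param w_means Tibble with `participant_id` and `w` (e.g. from
#'   [participant_weights()]).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return Tibble with `term`, `estimate`, `conf_low`, `conf_high`,
#'   `excludes_zero`.
#' @export
adjustment_regression <- function(trials, w_means, n_boot = 1000L,
                                  seed = 1L) {
  if (!"estimation_adjustment" %in% names(trials)) {
    trials <- trial_statistics(trials)
  }
  df <- dplyr::inner_join(trials, w_means, by = "participant_id")
  if (nrow(df) == 0L) stop("no overlap between trials and weights",
                           call. = FALSE)
  df$abs_adj <- abs(df$estimation_adjustment)
  df$condition <- factor(df$condition,
                         levels = intersect(shape_conditions(),
                                            unique(df$condition)))
  form <- if (nlevels(df$condition) > 1L) {
    abs_adj ~ w * condition
  } else {
    warning("single condition in data: fitting reduced model |adj| ~ w",
            call. = FALSE)
    abs_adj ~ w
  }
  fit <- stats::lm(form, data = df)
  est <- stats::coef(fit)

  set.seed(seed)
  by_p <- split(seq_len(nrow(df)), df$participant_id)
  boot <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    take <- unlist(by_p[sample.int(length(by_p), replace = TRUE)],
                   use.names = FALSE)
    cb <- tryCatch(stats::coef(stats::lm(form, data = df[take, ])),
                   error = function(e) rep(NA_real_, length(est)))
    if (length(cb) == length(est)) boot[b, ] <- cb
  }
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  tibble::tibble(
    term = names(est), estimate = unname(est),
    conf_low = ci[1, ], conf_high = ci[2, ],
    excludes_zero = ci[1, ] > 0 | ci[2, ] < 0
  )
}
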
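test_that("allocation log-likelihood matches independent evaluations", {
  gu <- bin_probabilities("uniform")
  gn <- bin_probabilities("negative")
  # single draw, f = u = g: log(0.2) regardless of w
  for (w in c(0, 0.4, 1)) {
    expect_equal(allocation_loglik(c(1, 0, 0, 0, 0), gu, w), log(0.2),
                 tolerance = 1e-12)
  }
  # w = 1: all mass in one bin, multinomial coefficient 1
  expect_equal(allocation_loglik(c(0, 0, 0, 0, 10), gn, 1), 10 * log(0.2),
               tolerance = 1e-12)
  # brute-force mass at f(w = 0.5)
  f <- 0.5 * gn + 0.5 * 0.2
  counts <- c(0, 1, 1, 3, 5)
  brute <- lgamma(11) - sum(lgamma(counts + 1)) + sum(counts * log(f))
  expect_equal(allocation_loglik(counts, gn, 0.5), brute, tolerance = 1e-10)
  # and against the base-R multinomial density as a second, independent route
  for (w in c(0, 0.17, 0.83)) {
    expect_equal(allocation_loglik(counts, gn, w),
                 dmultinom(counts, prob = mixture_probs(gn, w), log = TRUE),
                 tolerance = 1e-10)
  }
  expect_error(allocation_loglik(c(-1, 0, 0, 0, 11), gn, 0.5),
               "non-negative")
})

test_that("likelihood endpoints equal the pure-histogram multinomials", {
  gn <- bin_probabilities("negative")
  counts <- c(2, 3, 1, 4, 10)
  expect_equal(allocation_loglik(counts, gn, 0),
               dmultinom(counts, prob = gn, log = TRUE), tolerance = 1e-12)
  expect_equal(allocation_loglik(counts, gn, 1),
               dmultinom(counts, prob = rep(0.2, 5), log = TRUE),
               tolerance = 1e-12)
})

test_that("fence_data collapses trials into sufficient statistics", {
  trials <- dplyr::bind_rows(
    trial_row(1, 1, "negative", c(0L, 1L, 1L, 3L, 5L)),
    trial_row(1, 2, "positive", c(5L, 3L, 1L, 1L, 0L)),
    trial_row(1, 3, "uniform", c(2L, 2L, 2L, 2L, 2L)),
    trial_row(2, 1, "negative", c(1L, 1L, 2L, 3L, 3L))
  )
  dat <- fence_data(trials)
  expect_identical(dat$participant_id, c(1L, 2L))
  expect_equal(dat$C_neg[1, ], c(0, 1, 1, 3, 5))
  expect_equal(dat$C_pos[1, ], c(5, 3, 1, 1, 0))
  expect_equal(dat$C_pos[2, ], rep(0, 5))
  # uniform trials carry no weight information and are excluded
  expect_equal(sum(dat$C_neg[1, ]) + sum(dat$C_pos[1, ]), 20)
  uniform_only <- trial_row(1, 1, "uniform", c(2L, 2L, 2L, 2L, 2L))
  expect_error(fence_data(uniform_only), "no informative trials")
})

test_that("log_posterior matches term-by-term brute-force evaluation", {
  trials <- dplyr::bind_rows(
    trial_row(1, 1, "negative", c(0L, 1L, 1L, 3L, 5L)),
    trial_row(2, 1, "positive", c(6L, 2L, 1L, 1L, 0L))
  )
  dat <- fence_data(trials)
  gn <- bin_probabilities("negative")
  gp <- bin_probabilities("positive")
  ldt <- function(x, m, s) {
    dnorm(x, m, s, log = TRUE) - log(pnorm(1, m, s) - pnorm(0, m, s))
  }
  w <- c(0.3, 0.65); mu <- 0.45; sig <- 0.25
  manual <- allocation_loglik(c(0, 1, 1, 3, 5), gn, w[1]) +
    allocation_loglik(c(6, 2, 1, 1, 0), gp, w[2]) +
    ldt(w[1], mu, sig) + ldt(w[2], mu, sig) +
    ldt(mu, 0.5, 1) + log(2) + dnorm(sig, 0, 1, log = TRUE)
  expect_equal(log_posterior(dat, w, mu, sig), manual, tolerance = 1e-10)
  # density ratio between two points also matches (constants cancel)
  w2 <- c(0.5, 0.5)
  manual2 <- allocation_loglik(c(0, 1, 1, 3, 5), gn, w2[1]) +
    allocation_loglik(c(6, 2, 1, 1, 0), gp, w2[2]) +
    ldt(w2[1], 0.6, 0.4) + ldt(w2[2], 0.6, 0.4) +
    ldt(0.6, 0.5, 1) + log(2) + dnorm(0.4, 0, 1, log = TRUE)
  expect_equal(log_posterior(dat, w, mu, sig) -
                 log_posterior(dat, w2, 0.6, 0.4),
               manual - manual2, tolerance = 1e-10)
  # support boundaries
  expect_identical(log_posterior(dat, w, mu, -1), -Inf)
  expect_identical(log_posterior(dat, c(1.2, 0.5), mu, sig), -Inf)
  # w at 0 stays finite: g has no zero-probability bin
  expect_true(is.finite(log_posterior(dat, c(0, 0.5), mu, sig)))
})

test_that("MCMC matches grid integration on a tiny instance", {
  trials <- trial_row(1, 1, "negative", c(0L, 1L, 1L, 3L, 5L))
  dat <- fence_data(trials)
  # deterministic oracle: integrate the joint posterior over a dense grid
  wg <- seq(0.0005, 0.9995, length.out = 300)
  mg <- seq(0.0025, 0.9975, length.out = 120)
  sg <- seq(0.01, 4, length.out = 120)
  gn <- bin_probabilities("negative")
  lw <- vapply(wg, function(w) allocation_loglik(c(0, 1, 1, 3, 5), gn, w),
               numeric(1))
  lpm <- dnorm(mg, 0.5, 1, log = TRUE) -
    log(pnorm(1, 0.5, 1) - pnorm(0, 0.5, 1))
  lps <- log(2) + dnorm(sg, 0, 1, log = TRUE)
  tot <- 0; totw <- 0
  for (i in seq_along(mg)) {
    for (j in seq_along(sg)) {
      lpr <- dnorm(wg, mg[i], sg[j], log = TRUE) -
        log(pnorm(1, mg[i], sg[j]) - pnorm(0, mg[i], sg[j]))
      dens <- exp(lw + lpr + lpm[i] + lps[j])
      tot <- tot + sum(dens)
      totw <- totw + sum(wg * dens)
    }
  }
  oracle_mean <- totw / tot
  fit <- suppressWarnings(
    fit_hierarchical(trials, mcmc_config(n_iterations = 4000,
                                         n_warmup = 2000, seed = 3))
  )
  mcmc_mean <- participant_weights(fit)$w
  expect_lt(abs(mcmc_mean - oracle_mean), 0.02)
})

test_that("single-participant posterior tracks the maximum-likelihood w", {
  # many identical trials: posterior concentrates near the grid-search MLE
  counts <- c(1L, 1L, 2L, 3L, 3L)
  trials <- dplyr::bind_rows(lapply(1:20, function(t) {
    trial_row(1, t, "negative", counts, estimate_raw = 40 + t)
  }))
  gn <- bin_probabilities("negative")
  wg <- seq(0.001, 0.999, length.out = 2000)
  ll <- vapply(wg, function(w) {
    20 * allocation_loglik(counts, gn, w)
  }, numeric(1))
  mle <- wg[which.max(ll)]
  fit <- suppressWarnings(
    fit_hierarchical(trials, mcmc_config(n_iterations = 3000,
                                         n_warmup = 1500, seed = 9))
  )
  expect_lt(abs(participant_weights(fit)$w - mle), 0.05)
})

test_that("hierarchical fit recovers the population weight at scale", {
  ex <- simulate_experiment(experiment_design(n_participants = 145),
                            population_params(0.5, 0.2), seed = 11)
  kept <- apply_exclusions(ex$trials)$trials
  fit <- fit_hierarchical(kept, mcmc_config(seed = 11))
  s <- fit$summary
  mu_row <- s[s$parameter == "mu_w", ]
  expect_lt(abs(mu_row$mean - 0.5), 0.05)
  expect_true(mu_row$ci_low <= 0.5 && 0.5 <= mu_row$ci_high)
  expect_lte(mu_row$rhat, 1.05)
  expect_gt(mu_row$ess, 100)
  sig_row <- s[s$parameter == "sigma_w", ]
  expect_lt(abs(sig_row$mean - 0.2), 0.07)
  # all stored weights live on [0, 1]; sigma draws positive
  expect_true(all(fit$draws$w >= 0 & fit$draws$w <= 1))
  expect_true(all(fit$draws$sigma_w > 0))
  # credible intervals contain the posterior means
  expect_true(all(s$ci_low <= s$mean & s$mean <= s$ci_high))
  # hierarchical shrinkage: per-participant posterior means correlate with truth
  pw <- participant_weights(fit)
  expect_gt(cor(pw$w, ex$agents$w[pw$participant_id]), 0.6)
})

test_that("shrinkage pulls individual weights toward mu_w as sigma_w -> 0", {
  des <- experiment_design(n_participants = 40)
  ex <- simulate_experiment(des, population_params(0.5, 0.01), seed = 15)
  fit <- suppressWarnings(
    fit_hierarchical(apply_exclusions(ex$trials)$trials,
                     mcmc_config(seed = 15))
  )
  pw <- participant_weights(fit)
  mu_hat <- fit$summary$mean[fit$summary$parameter == "mu_w"]
  expect_lt(max(abs(pw$w - mu_hat)), 0.1)
})

test_that("adjustment regression flags the weight effect when present", {
  des <- experiment_design(n_participants = 60)
  ex <- simulate_experiment(des, population_params(0.5, 0.25),
                            kappa = 0.8, sigma_e = 0.01, seed = 31)
  st <- trial_statistics(apply_exclusions(ex$trials)$trials)
  truth <- tibble::tibble(participant_id = ex$agents$participant_id,
                          w = ex$agents$w)
  reg <- adjustment_regression(st, truth, n_boot = 300, seed = 1)
  wrow <- reg[reg$term == "w", ]
  expect_gt(wrow$estimate, 0)
  expect_true(wrow$excludes_zero)

  # kappa = 0: no adjustment signal, w interval includes 0
  ex0 <- simulate_experiment(des, population_params(0.5, 0.25),
                             kappa = 0, sigma_e = 0.02, seed = 32)
  st0 <- trial_statistics(apply_exclusions(ex0$trials)$trials)
  truth0 <- tibble::tibble(participant_id = ex0$agents$participant_id,
                           w = ex0$agents$w)
  reg0 <- adjustment_regression(st0, truth0, n_boot = 300, seed = 1)
  expect_false(reg0$excludes_zero[reg0$term == "w"])

  # uniform-only data: reduced model with no weight effect
  uni <- st[st$condition == "uniform", ]
  expect_warning(regu <- adjustment_regression(uni, truth, n_boot = 300,
                                               seed = 1),
                 "single condition")
  expect_false(regu$excludes_zero[regu$term == "w"])
})

test_that("convergence problems are flagged, not silent", {
  # two chains, far too few iterations on a hard posterior
  ex <- simulate_experiment(experiment_design(n_participants = 30),
                            population_params(0, 0), seed = 5)
  expect_warning(
    fit_hierarchical(apply_exclusions(ex$trials)$trials,
                     mcmc_config(n_chains = 2, n_iterations = 60,
                                 n_warmup = 30, seed = 5)),
    "convergence|Rhat"
  )
})
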
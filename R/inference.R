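#' Multinomial log-likelihood of an allocation under the fencing mixture
#'
#' Log probability of observing bin counts from one trial under allocation
#' probabilities `f(w) = (1 - w) g + w u`, including the multinomial
#' coefficient. At `w = 0` the likelihood is the multinomial under the
#' objective histogram `g` exactly; at `w = 1`, under the uniform histogram.
#' Returns `-Inf` when a count falls in a zero-probability bin.
#'
#' @param counts Non-negative integer vector of bin counts (sums to the
#'   trial budget).
#' @param g Objective bin probabilities.
#' @param w Mixture weight in \[0, 1\].
#' @return Log-likelihood value.
#' @export
allocation_loglik <- function(counts, g, w) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("`counts` must sum to at least 1", call. = FALSE)
  f <- mixture_probs(g, w)
  lf <- ifelse(counts == 0, 0, counts * log(f))
  if (any(!is.finite(lf))) return(-Inf)
  lgamma(n + 1) - sum(lgamma(counts + 1)) + sum(lf)
}

#' Assemble per-participant likelihood data from a trial table
#'
#' Collapses the skewed-condition trials of each participant into sufficient
#' statistics for the mixture likelihood: summed bin counts per skewed
#' condition plus the (parameter-free) sum of multinomial coefficients.
#' Uniform-condition trials are dropped — there `f(w) = g` for every `w`, so
#' they carry no information about the weight.
#'
#' @inheritParams apply_exclusions
#' @return A list of class `fence_data` with fields `participant_id`,
#'   `C_neg`, `C_pos` (participants x bins count matrices), `lconst`
#'   (per-participant summed log multinomial coefficients), `g_neg`, `g_pos`.
#' @export
fence_data <- function(trials) {
  skew <- trials[trials$condition %in% c("negative", "positive"), ,
                 drop = FALSE]
  if (nrow(skew) == 0L) {
    stop("no informative trials: all trials are uniform-condition",
         call. = FALSE)
  }
  nb <- length(bin_cols(trials))
  ids <- sort(unique(trials$participant_id))
  no_skew <- setdiff(ids, unique(skew$participant_id))
  if (length(no_skew) > 0L) {
    warning(length(no_skew),
            " participant(s) without skewed trials dropped from the fit")
    ids <- setdiff(ids, no_skew)
  }
  cm <- counts_matrix(skew)
  lc <- lgamma(rowSums(cm) + 1) - rowSums(lgamma(cm + 1))
  sum_by <- function(cond) {
    m <- matrix(0, length(ids), nb)
    sel <- skew$condition == cond
    if (any(sel)) {
      agg <- rowsum(cm[sel, , drop = FALSE], skew$participant_id[sel])
      m[match(rownames(agg), as.character(ids)), ] <- agg
    }
    m
  }
  structure(
    list(participant_id = ids,
         C_neg = sum_by("negative"), C_pos = sum_by("positive"),
         lconst = as.numeric(rowsum(lc, skew$participant_id)[
           match(ids, sort(unique(skew$participant_id))), 1]),
         g_neg = bin_probabilities("negative", nb),
         g_pos = bin_probabilities("positive", nb)),
    class = "fence_data"
  )
}

# per-participant log-likelihood at participant-specific weights W
loglik_by_participant <- function(data, W) {
  nb <- length(data$g_neg)
  Fn <- (1 - W) %o% data$g_neg + W / nb
  Fp <- (1 - W) %o% data$g_pos + W / nb
  data$lconst + rowSums(data$C_neg * log(Fn)) + rowSums(data$C_pos * log(Fp))
}

ldtruncnorm01 <- function(x, mean, sd) {
  stats::dnorm(x, mean, sd, log = TRUE) -
    log(stats::pnorm(1, mean, sd) - stats::pnorm(0, mean, sd))
}

# weakly informative hyperpriors
lprior_mu <- function(mu) {
  if (mu <= 0 || mu >= 1) return(-Inf)
  ldtruncnorm01(mu, 0.5, 1)
}
lprior_sigma <- function(sigma) {
  if (sigma <= 0) return(-Inf)
  log(2) + stats::dnorm(sigma, 0, 1, log = TRUE)
}

#' Hierarchical log-posterior of the fencing model
#'
#' Joint log density (up to nothing — all normalizing constants of the
#' priors are included) of the participant weights and hyperparameters given
#' the allocation counts: multinomial mixture likelihood per participant,
#' truncated-Normal(`mu_w`, `sigma_w`) population prior on each `w_i` over
#' \[0, 1\], a Normal(0.5, 1) prior truncated to \[0, 1\] on `mu_w`, and a
#' Half-Normal(1) prior on `sigma_w`.
#'
#' @param data A [fence_data()] object.
#' @param w Vector of participant weights, one per participant in `data`.
#' @param mu_w,sigma_w Population parameters.
#' @return Log-posterior value (`-Inf` outside the support).
#' @export
log_posterior <- function(data, w, mu_w, sigma_w) {
  stopifnot(inherits(data, "fence_data"),
            length(w) == length(data$participant_id))
  if (sigma_w <= 0 || any(w < 0 | w > 1) || mu_w <= 0 || mu_w >= 1) {
    return(-Inf)
  }
  sum(loglik_by_participant(data, w)) +
    sum(ldtruncnorm01(w, mu_w, sigma_w)) +
    lprior_mu(mu_w) + lprior_sigma(sigma_w)
}

#' MCMC configuration
#'
#' Defaults follow the study's fitting protocol: four chains of 2000
#' iterations each, the first 1000 discarded as adaptive warmup.
#'
#' @param n_chains Number of chains (>= 2, for split-Rhat).
#' @param n_iterations Iterations per chain, warmup included.
#' @param n_warmup Warmup (adaptation) iterations per chain.
#' @param seed Integer master seed; chain seeds derive from it.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iterations = 2000L,
                        n_warmup = 1000L, seed = 1L) {
  stopifnot(n_chains >= 2, n_warmup < n_iterations)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# one chain of adaptive random-walk Metropolis-within-Gibbs on transformed
# parameters: logit(w_i), logit(mu_w), log(sigma_w). Proposal scales adapt
# during warmup toward ~0.44 acceptance (scalar-update optimum).
run_chain <- function(data, config, chain_seed) {
  set.seed(chain_seed)
  P <- length(data$participant_id)
  n_iter <- config$n_iterations
  n_warm <- config$n_warmup
  n_keep <- n_iter - n_warm

  z <- stats::qlogis(stats::runif(P, 0.25, 0.75))
  lm <- stats::qlogis(stats::runif(1, 0.35, 0.65))
  ls <- log(stats::runif(1, 0.15, 0.5))
  s_w <- rep(1, P); s_mu <- 0.5; s_sig <- 0.5

  w <- stats::plogis(z)
  mu <- stats::plogis(lm)
  sig <- exp(ls)
  ll <- loglik_by_participant(data, w)
  # per-participant target on the transformed scale (prior + Jacobian)
  wprior <- function(w, mu, sig) ldtruncnorm01(w, mu, sig) + log(w) + log1p(-w)
  lp_w <- ll + wprior(w, mu, sig)

  W_draws <- matrix(NA_real_, n_keep, P)
  mu_draws <- numeric(n_keep)
  sig_draws <- numeric(n_keep)

  for (t in seq_len(n_iter)) {
    # participant weights: independent componentwise proposals
    z_new <- z + stats::rnorm(P) * s_w
    w_new <- stats::plogis(z_new)
    ll_new <- loglik_by_participant(data, w_new)
    lp_new <- ll_new + wprior(w_new, mu, sig)
    acc <- log(stats::runif(P)) < lp_new - lp_w
    z[acc] <- z_new[acc]; w[acc] <- w_new[acc]
    ll[acc] <- ll_new[acc]; lp_w[acc] <- lp_new[acc]

    # mu_w
    lm_new <- lm + stats::rnorm(1) * s_mu
    mu_new <- stats::plogis(lm_new)
    num <- sum(ldtruncnorm01(w, mu_new, sig)) + lprior_mu(mu_new) +
      log(mu_new) + log1p(-mu_new)
    den <- sum(ldtruncnorm01(w, mu, sig)) + lprior_mu(mu) +
      log(mu) + log1p(-mu)
    acc_mu <- log(stats::runif(1)) < num - den
    if (acc_mu) { lm <- lm_new; mu <- mu_new }

    # sigma_w
    ls_new <- ls + stats::rnorm(1) * s_sig
    sig_new <- exp(ls_new)
    num <- sum(ldtruncnorm01(w, mu, sig_new)) + lprior_sigma(sig_new) + ls_new
    den <- sum(ldtruncnorm01(w, mu, sig)) + lprior_sigma(sig) + ls
    acc_sig <- log(stats::runif(1)) < num - den
    if (acc_sig) { ls <- ls_new; sig <- sig_new }

    # population parameters moved: refresh the cached weight targets
    if (acc_mu || acc_sig) lp_w <- ll + wprior(w, mu, sig)

    if (t <= n_warm) {
      gam <- min(0.25, 1 / sqrt(t))
      s_w <- s_w * exp(gam * (as.numeric(acc) - 0.44))
      s_mu <- s_mu * exp(gam * (as.numeric(acc_mu) - 0.44))
      s_sig <- s_sig * exp(gam * (as.numeric(acc_sig) - 0.44))
    } else {
      k <- t - n_warm
      W_draws[k, ] <- w
      mu_draws[k] <- mu
      sig_draws[k] <- sig
    }
  }
  list(w = W_draws, mu_w = mu_draws, sigma_w = sig_draws)
}

#' Split-Rhat potential scale reduction
#'
#' @param draws Matrix of post-warmup draws, iterations x chains.
#' @return The split-chain potential scale reduction statistic.
#' @export
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size, summed over chains, with the
#' sum truncated at the first negative pair of autocorrelations (Geyer's
#' initial positive sequence).
#'
#' @inheritParams split_rhat
#' @return Estimated effective number of draws.
#' @export
ess_basic <- function(draws) {
  per_chain <- function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = TRUE)$acf[-1]
    s <- 0
    for (k in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[k] + ac[k + 1]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  }
  sum(apply(draws, 2L, per_chain))
}

#' Fit the hierarchical fencing model
#'
#' Samples the joint posterior of the participant mixture weights `w_i` and
#' the population parameters (`mu_w`, `sigma_w`) given allocation counts,
#' using an adaptive random-walk Metropolis-within-Gibbs sampler on
#' transformed parameters. Uniform-condition trials are excluded (they are
#' uninformative about `w`); both budget arms are pooled into one fit. A
#' warning is raised when split-Rhat of `mu_w` or `sigma_w` exceeds 1.05.
#'
#' @param trials Trial tibble (pass through [apply_exclusions()] first), or
#'   a prebuilt [fence_data()] object.
#' @param config An [mcmc_config()].
#' @return An object of class `fence_fit`: `summary` (tibble with posterior
#'   mean, 95% credible interval, Rhat and ESS per parameter), `draws`
#'   (post-warmup arrays), `converged`, `data`, `config`.
#' @export
fit_hierarchical <- function(trials, config = mcmc_config()) {
  data <- if (inherits(trials, "fence_data")) trials else fence_data(trials)
  stopifnot(inherits(config, "mcmc_config"))
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    run_chain(data, config, chain_seed = config$seed * 1000L + ch)
  })
  n_keep <- config$n_iterations - config$n_warmup
  P <- length(data$participant_id)
  mu_m <- sapply(chains, `[[`, "mu_w")
  sig_m <- sapply(chains, `[[`, "sigma_w")
  w_arr <- array(NA_real_, c(n_keep, config$n_chains, P))
  for (ch in seq_along(chains)) w_arr[, ch, ] <- chains[[ch]]$w

  summarize <- function(m, name) {
    pool <- as.numeric(m)
    tibble::tibble(parameter = name, mean = mean(pool),
                   ci_low = stats::quantile(pool, 0.025, names = FALSE),
                   ci_high = stats::quantile(pool, 0.975, names = FALSE),
                   rhat = split_rhat(m), ess = ess_basic(m))
  }
  summ <- dplyr::bind_rows(
    summarize(mu_m, "mu_w"),
    summarize(sig_m, "sigma_w"),
    dplyr::bind_rows(lapply(seq_len(P), function(i) {
      summarize(w_arr[, , i],
                sprintf("w[%d]", data$participant_id[i]))
    }))
  )
  conv <- all(summ$rhat[summ$parameter %in% c("mu_w", "sigma_w")] <= 1.05)
  if (!conv) {
    warning("convergence not reached: split-Rhat > 1.05 for a population ",
            "parameter; consider more iterations", call. = FALSE)
  }
  structure(
    list(summary = summ,
         draws = list(mu_w = mu_m, sigma_w = sig_m, w = w_arr),
         converged = conv, data = data, config = config),
    class = "fence_fit"
  )
}

#' @export
print.fence_fit <- function(x, ...) {
  cat(sprintf("<fence_fit> %d participants, %d chains x %d draws%s\n",
              length(x$data$participant_id), x$config$n_chains,
              x$config$n_iterations - x$config$n_warmup,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(as.data.frame(x$summary[x$summary$parameter %in%
                                  c("mu_w", "sigma_w"), ]), row.names = FALSE)
  invisible(x)
}

#' Posterior means of the participant weights
#'
#' @param fit A [fit_hierarchical()] result.
#' @return Tibble with `participant_id` and posterior mean `w`.
#' @export
participant_weights <- function(fit) {
  stopifnot(inherits(fit, "fence_fit"))
  tibble::tibble(
    participant_id = fit$data$participant_id,
    w = apply(fit$draws$w, 3L, mean)
  )
}
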
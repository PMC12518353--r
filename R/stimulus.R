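#' Shape conditions of the rating task
#'
#' The task environment uses three beta-distributed stimulus shapes on the
#' normalized support \[0, 1\]: negatively skewed Beta(3, 1), positively
#' skewed Beta(1, 3), and uniform Beta(1, 1). `shape_conditions()` lists the
#' valid labels; `shape_params()` maps a label to its beta shape parameters.
#'
#' @param condition One of `"negative"`, `"positive"`, `"uniform"`.
#' @return `shape_params()` returns a named numeric vector with elements
#'   `alpha` and `beta`.
#' @examples
#' shape_params("negative")
#' @export
shape_params <- function(condition) {
  condition <- match.arg(condition, shape_conditions())
  switch(condition,
    negative = c(alpha = 3, beta = 1),
    positive = c(alpha = 1, beta = 3),
    uniform  = c(alpha = 1, beta = 1)
  )
}

#' @rdname shape_params
#' @export
shape_conditions <- function() c("negative", "positive", "uniform")

#' Exact bin probabilities of a binned beta stimulus
#'
#' Partitions the normalized support \[0, 1\] into `n_bins` equal-width
#' intervals and returns the probability mass of each interval under the
#' condition's beta distribution, computed from the exact beta CDF. These are
#' the per-bin probabilities displayed on the task histogram and the shares a
#' proportional stratified sampler would target.
#'
#' @inheritParams shape_params
#' @param n_bins Number of equal-width bins (default 5, the task design).
#' @return Numeric vector of length `n_bins` summing to 1.
#' @examples
#' bin_probabilities("negative")   # (0.008, 0.056, 0.152, 0.296, 0.488)
#' @export
bin_probabilities <- function(condition, n_bins = 5L) {
  if (length(n_bins) != 1L || !is.finite(n_bins) || n_bins < 2 ||
      n_bins != round(n_bins)) {
    stop("`n_bins` must be a single integer >= 2 (malformed task design)",
         call. = FALSE)
  }
  p <- shape_params(condition)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  diff(stats::pbeta(edges, p[["alpha"]], p[["beta"]]))
}

#' Construct a binned, scaled beta stimulus distribution
#'
#' A `binned_dist` bundles everything the simulator and the statistics need
#' about one trial's stimulus: the shape condition, the trial's scale
#' multiplier (positivity-score units), the bin edges on the normalized scale,
#' the exact bin probabilities `g`, the within-bin conditional means `m` and
#' variances `s2`, and the true mean `mu`. All moments are exact beta
#' integrals, not approximations.
#'
#' @inheritParams bin_probabilities
#' @param multiplier Scale factor in \[50, 100\] mapping the normalized
#'   support to positivity scores.
#' @return An object of class `binned_dist`.
#' @examples
#' d <- binned_distribution("negative", multiplier = 80)
#' d$g
#' sum(d$g * d$m) - d$mu   # law of total expectation, ~0
#' @export
binned_distribution <- function(condition, multiplier = 75, n_bins = 5L) {
  condition <- match.arg(condition, shape_conditions())
  if (length(multiplier) != 1L || !is.finite(multiplier) ||
      multiplier < 50 || multiplier > 100) {
    stop("`multiplier` must be a single value in [50, 100]", call. = FALSE)
  }
  p <- shape_params(condition)
  a <- p[["alpha"]]; b <- p[["beta"]]
  edges <- seq(0, 1, length.out = n_bins + 1L)
  g <- bin_probabilities(condition, n_bins)
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  # E[X | bin] and E[X^2 | bin] from shifted-shape beta CDFs:
  # integral of x^j dBeta(a,b) over [lo,hi] equals
  # prod_{i<j}((a+i)/(a+b+i)) * (F_{a+j,b}(hi) - F_{a+j,b}(lo))
  mu_full <- a / (a + b)
  ex1 <- mu_full * (stats::pbeta(hi, a + 1, b) - stats::pbeta(lo, a + 1, b)) / g
  ex2 <- mu_full * (a + 1) / (a + b + 1) *
    (stats::pbeta(hi, a + 2, b) - stats::pbeta(lo, a + 2, b)) / g
  structure(
    list(
      condition = condition, alpha = a, beta = b,
      multiplier = multiplier, n_bins = as.integer(n_bins),
      edges = edges, g = g, m = ex1, s2 = ex2 - ex1^2,
      mu = mu_full
    ),
    class = "binned_dist"
  )
}

#' @export
print.binned_dist <- function(x, ...) {
  cat(sprintf("<binned_dist> %s Beta(%g, %g), %d bins, multiplier %.3f\n",
              x$condition, x$alpha, x$beta, x$n_bins, x$multiplier))
  cat("  g :", paste(signif(x$g, 4), collapse = " "), "\n")
  cat("  mu:", signif(x$mu, 4), "(normalized)\n")
  invisible(x)
}

#' True mean of a stimulus distribution
#'
#' @param dist A [binned_distribution()].
#' @param normalized If `TRUE` (default) return the mean on the \[0, 1\]
#'   scale (`alpha / (alpha + beta)`); otherwise on the positivity-score scale
#'   (multiplied by the trial multiplier).
#' @return A single numeric value.
#' @export
true_mean <- function(dist, normalized = TRUE) {
  stopifnot(inherits(dist, "binned_dist"))
  if (normalized) dist$mu else dist$mu * dist$multiplier
}

#' Conditional moments of one bin
#'
#' Mean and variance of the stimulus beta distribution restricted to bin `k`,
#' on the normalized scale.
#'
#' @inheritParams true_mean
#' @param k Bin index in `1:dist$n_bins`.
#' @return Named numeric vector `c(mean = , variance = )`.
#' @export
bin_conditional_moments <- function(dist, k) {
  stopifnot(inherits(dist, "binned_dist"))
  if (length(k) != 1L || k < 1 || k > dist$n_bins || k != round(k)) {
    stop("bin index `k` out of range", call. = FALSE)
  }
  c(mean = dist$m[k], variance = dist$s2[k])
}

#' Draw positivity scores from one bin
#'
#' Samples from the stimulus beta distribution truncated to bin `k` by
#' inverse-CDF transform, and scales by the trial multiplier. Bins are
#' half-open `[a, b)` except the last, which is closed at 1; for a continuous
#' distribution the edge convention has zero probability mass.
#'
#' @inheritParams bin_conditional_moments
#' @param n Number of draws.
#' @param quantiles Optional vector of uniform quantiles in \[0, 1\] to use
#'   instead of fresh random numbers (deterministic draws; used for testing
#'   and for reproducible replay).
#' @return Tibble with columns `bin`, `value` (normalized), `raw`
#'   (positivity-score scale).
#' @export
draw_from_bin <- function(dist, k, n = 1L, quantiles = NULL) {
  stopifnot(inherits(dist, "binned_dist"))
  if (length(k) != 1L || k < 1 || k > dist$n_bins || k != round(k)) {
    stop("bin index `k` out of range", call. = FALSE)
  }
  u <- if (is.null(quantiles)) stats::runif(n) else quantiles
  flo <- stats::pbeta(dist$edges[k], dist$alpha, dist$beta)
  fhi <- stats::pbeta(dist$edges[k + 1L], dist$alpha, dist$beta)
  x <- stats::qbeta(flo + u * (fhi - flo), dist$alpha, dist$beta)
  tibble::tibble(bin = as.integer(k), value = x, raw = x * dist$multiplier)
}

#' Generate one trial's stimulus
#'
#' Draws the trial scale multiplier uniformly on \[50, 100\] (masking the
#' range of positivity scores across trials, as in the task design) and
#' returns the fully populated [binned_distribution()].
#'
#' @inheritParams bin_probabilities
#' @return A `binned_dist`.
#' @export
make_trial_stimulus <- function(condition, n_bins = 5L) {
  binned_distribution(condition, multiplier = stats::runif(1, 50, 100),
                      n_bins = n_bins)
}
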
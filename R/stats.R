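#' Bootstrap difference of group means
#'
#' Resamples each group with replacement at its own size, records
#' mean(a*) - mean(b*) `n_resamples` times, and returns the observed
#' difference with the empirical central 95% interval. The difference is
#' flagged significantly positive when the interval excludes zero from
#' below.
#'
#' @param a,b numeric samples (both non-empty).
#' @param n_resamples number of bootstrap resamples (>= 100).
#' @param seed integer seed (optional; caller's RNG untouched).
#' @return List with `mean_difference`, `ci` (2.5% and 97.5% empirical
#'   quantiles), `significant_positive`, and `n_resamples`.
#' @export
bootstrap_diff_means <- function(a, b, n_resamples = 5000, seed = NULL) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (n_resamples < 100) stop("n_resamples must be >= 100")
  with_seed(seed, {
    na <- length(a); nb <- length(b)
    ma <- colMeans(matrix(sample(a, na * n_resamples, replace = TRUE), na))
    mb <- colMeans(matrix(sample(b, nb * n_resamples, replace = TRUE), nb))
    d <- ma - mb
    ci <- unname(stats::quantile(d, c(0.025, 0.975)))
    list(mean_difference = mean(a) - mean(b),
         ci = ci,
         significant_positive = ci[1] > 0,
         n_resamples = n_resamples)
  })
}

#' Ratio of group means with bootstrap-propagated error
#'
#' Bootstraps each group's mean, fits a Gaussian to each bootstrap
#' distribution (its mean and standard deviation), and reports the
#' observed ratio r = mean(a)/mean(b) with standard error by first-order
#' propagation: r * sqrt((sd_a/mean_a)^2 + (sd_b/mean_b)^2), where sd_a,
#' sd_b are the bootstrap standard deviations of the two means.
#'
#' @inheritParams bootstrap_diff_means
#' @return List with `ratio`, `se`, and the per-group bootstrap mean
#'   standard deviations `sd_mean_a`, `sd_mean_b`.
#' @export
ratio_of_means_bootstrap <- function(a, b, n_resamples = 5000, seed = NULL) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (n_resamples < 100) stop("n_resamples must be >= 100")
  mb0 <- mean(b)
  if (abs(mb0) < 1e-12 * (stats::sd(b) + abs(mean(a)) + 1))
    stop("denominator group mean is approximately zero")
  with_seed(seed, {
    na <- length(a); nb <- length(b)
    ma <- colMeans(matrix(sample(a, na * n_resamples, replace = TRUE), na))
    mb <- colMeans(matrix(sample(b, nb * n_resamples, replace = TRUE), nb))
    r <- mean(a) / mb0
    sa <- stats::sd(ma); sb <- stats::sd(mb)
    list(ratio = r,
         se = abs(r) * sqrt((sa / mean(a))^2 + (sb / mb0)^2),
         sd_mean_a = sa, sd_mean_b = sb)
  })
}

#' Two-sided Mann-Whitney U rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and
#' there are no ties; otherwise the tie-corrected normal approximation
#' (without continuity correction). The U statistic counts pairs (i, j)
#' with a_i > b_j (plus half-ties).
#'
#' @param a,b numeric samples (both non-empty).
#' @return List with `U` and `p_value`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
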
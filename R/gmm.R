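# one EM fit of a k-component 1-D Gaussian mixture from a given init;
# returns NULL on an ill-conditioned run
gmm_em_once <- function(x, mu0, var_floor, max_iter) {
  k <- length(mu0)
  n <- length(x)
  mu <- mu0
  v <- rep(stats::var(x), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sqrt(v[j])), numeric(n))
    dens <- matrix(dens, n, k)
    rs <- rowSums(dens)
    if (any(rs == 0) || any(!is.finite(rs))) return(NULL)
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8 * (1 + abs(ll))) break
    ll_old <- ll
  }
  if (!is.finite(ll)) return(NULL)
  list(mu = mu, var = v, w = w, loglik = ll)
}

# k-means++-style seeded draw of k initial means
init_means <- function(x, k) {
  mu <- numeric(k)
  mu[1] <- x[sample.int(length(x), 1)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(x, function(xi) min((xi - mu[1:(j - 1)])^2), numeric(1))
    if (sum(d2) == 0) mu[j] <- x[sample.int(length(x), 1)]
    else mu[j] <- x[sample.int(length(x), 1, prob = d2)]
  }
  mu
}

#' Fit and select a 1-D Gaussian mixture by BIC or AIC
#'
#' For each component count k = 1..`k_max`, runs `replicates`
#' expectation-maximization fits from seeded random (k-means++-style)
#' initializations, keeps the best log-likelihood, and selects the k
#' minimizing the chosen information criterion. Component variances are
#' floored at 1e-6 times the sample variance; a k whose replicates all
#' end ill-conditioned is excluded (with a warning), effectively
#' reducing `k_max`.
#'
#' @param samples numeric intensity samples; needs more than `k_max`
#'   values.
#' @param k_max largest component count tried.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param replicates random restarts per k (default 100).
#' @param max_iter EM iteration cap per fit (default 500).
#' @param seed integer seed for the replicate initializations (optional;
#'   the caller's RNG stream is untouched).
#' @return A `gmm_model`: `k`, sorted `means`, `variances`, `weights`,
#'   `loglik`, `bic`, `aic`, the per-k criterion table `selection`, and
#'   the fit settings.
#' @export
select_gmm <- function(samples, k_max, criterion = c("BIC", "AIC"),
                       replicates = 100, max_iter = 500, seed = NULL) {
  criterion <- match.arg(criterion)
  x <- as.numeric(samples)
  if (any(!is.finite(x))) stop("samples must be finite")
  if (k_max < 1) stop("k_max must be >= 1")
  if (length(x) < k_max + 1)
    stop("too few samples for the requested k_max")
  if (stats::var(x) == 0) stop("samples are constant")
  var_floor <- 1e-6 * stats::var(x)
  with_seed(seed, {
    fits <- vector("list", k_max)
    for (k in seq_len(k_max)) {
      best <- NULL
      for (rep in seq_len(replicates)) {
        f <- gmm_em_once(x, init_means(x, k), var_floor, max_iter)
        if (!is.null(f) && (is.null(best) || f$loglik > best$loglik))
          best <- f
      }
      fits[[k]] <- best
    }
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("all mixture fits were ill-conditioned")
    if (!all(ok))
      warning(sprintf(
        "component counts {%s} were ill-conditioned in every replicate and were excluded",
        paste(which(!ok), collapse = ", ")))
    n <- length(x)
    tab <- data.frame(k = which(ok))
    tab$loglik <- vapply(fits[ok], `[[`, numeric(1), "loglik")
    npar <- 3 * tab$k - 1
    tab$bic <- -2 * tab$loglik + npar * log(n)
    tab$aic <- -2 * tab$loglik + 2 * npar
    pick <- tab$k[which.min(if (criterion == "BIC") tab$bic else tab$aic)]
    f <- fits[[pick]]
    ord <- order(f$mu)
    structure(
      list(k = pick,
           means = f$mu[ord], variances = f$var[ord], weights = f$w[ord],
           loglik = f$loglik,
           bic = tab$bic[tab$k == pick], aic = tab$aic[tab$k == pick],
           criterion = criterion, selection = tab,
           replicates = replicates, max_iter = max_iter),
      class = "gmm_model")
  })
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture: k = %d (%s-selected), loglik %.2f\n",
              x$k, x$criterion, x$loglik))
  print(data.frame(mean = x$means, sd = sqrt(x$variances),
                   weight = x$weights))
  invisible(x)
}

#' Single-fluorophore intensity calibration from a mixture fit
#'
#' With mixture component means sorted ascending, the single-fluorophore
#' intensity is the spacing of the two smallest means,
#' g = mu(2) - mu(1), and the background offset implied by it is
#' b = mu(1) - g (so that mu(1) corresponds to one fluorophore after
#' background subtraction). Raw intensities normalize to copy-number
#' scale as (raw - b) / g.
#'
#' @param gmm a [select_gmm()] fit with at least two components.
#' @return A `calibration` list with `single_fluor_intensity` (g, counts)
#'   and `background` (b, counts).
#' @export
calibrate <- function(gmm) {
  stopifnot(inherits(gmm, "gmm_model"))
  if (gmm$k < 2)
    stop("calibration needs at least two mixture components")
  mu <- sort(gmm$means)
  g <- mu[2] - mu[1]
  if (g <= 0) stop("non-positive component spacing; cannot calibrate")
  structure(list(single_fluor_intensity = g, background = mu[1] - g),
            class = "calibration")
}

#' Normalize raw intensities to copy-number scale
#'
#' @param calibration a [calibrate()] result.
#' @param raw raw intensity samples (counts).
#' @return (raw - b) / g, dimensionless.
#' @export
normalize_intensities <- function(calibration, raw) {
  stopifnot(inherits(calibration, "calibration"))
  (raw - calibration$background) / calibration$single_fluor_intensity
}

#' Fraction of normalized intensities within a multiple of one fluorophore
#'
#' @param normalized normalized (copy-number scale) samples.
#' @param multiple inclusive upper bound (default 10).
#' @return Fraction in \[0, 1\].
#' @export
fraction_within <- function(normalized, multiple = 10) {
  if (length(normalized) == 0) stop("no samples")
  mean(normalized <= multiple)
}
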
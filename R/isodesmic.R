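#' Isodesmic self-association equilibrium
#'
#' An isodesmic model assumes that every monomer-addition step
#' \eqn{A_n + A_1 \rightleftharpoons A_{n+1}} has the same dissociation
#' constant K, regardless of oligomer length. With monomer concentration
#' m (nM) the oligomer concentrations are \eqn{c_n = m (m/K)^{n-1}} for
#' n up to the truncation order N. Two measurements close the system:
#' conservation of protomers, \eqn{\sum n c_n = c_{tot}}, and the
#' number-average species mass,
#' \eqn{M_1 \sum n c_n / \sum c_n = M_{avg}}.
#'
#' The solver reduces the system to one dimension: with \eqn{x = m/K},
#' the average-mass constraint
#' \eqn{\sum_{n=1}^{N} n x^{n-1} / \sum_{n=1}^{N} x^{n-1} = M_{avg}/M_1}
#' depends on x alone and is strictly increasing from 1 (at x = 0)
#' to N, so a bracketed root find gives a unique solution; m then follows
#' from conservation and K = m/x. K is reported as monomer squared over
#' dimer, \eqn{K_D = m^2/c_2}, which equals m/x.
#'
#' @param system an [isodesmic_system()] object.
#' @param observed_avg_mass measured number-average species mass in kDa.
#'   Must lie strictly between the monomer mass and `max_order` times the
#'   monomer mass.
#' @param mass_average `"number"` (the default, matching the model above)
#'   or `"weight"`, in which case the constraint uses the weight-average
#'   mass \eqn{M_1 \sum n^2 c_n / \sum n c_n}.
#'
#' @return A list with components
#'   \item{distribution}{a `species_distribution`: per-oligomer
#'     concentrations `concentrations` (nM, index = oligomer order),
#'     `number_average_mass` (kDa) and `protomer_sum` (nM).}
#'   \item{kd}{a `kd_estimate`: `kd` (nM), `max_order`, `residual`
#'     (relative error of the reproduced average mass) and
#'     `monomer_fraction_of_protomers`.}
#' @examples
#' sys <- isodesmic_system(710, 10, 11)
#' fit <- solve_isodesmic(sys, 15)
#' fit$kd$kd          # ~946.6 nM
#' @export
solve_isodesmic <- function(system, observed_avg_mass,
                            mass_average = c("number", "weight")) {
  stopifnot(inherits(system, "isodesmic_system"))
  mass_average <- match.arg(mass_average)
  m1 <- system$monomer_mass
  N <- system$max_order
  ctot <- system$total_protomer_conc
  if (!is.numeric(observed_avg_mass) || length(observed_avg_mass) != 1L ||
      !is.finite(observed_avg_mass))
    stop("observed_avg_mass must be a single finite number")
  if (N < 2L)
    stop("max_order must be at least 2 to infer a dissociation constant")
  if (observed_avg_mass <= m1)
    stop(sprintf(
      "infeasible average mass: %.6g kDa is <= the monomer mass %.6g kDa",
      observed_avg_mass, m1))
  if (observed_avg_mass >= m1 * N)
    stop(sprintf(
      "infeasible average mass: %.6g kDa is >= max_order * monomer mass = %.6g kDa",
      observed_avg_mass, m1 * N))

  r <- observed_avg_mass / m1
  n <- seq_len(N)
  ratio <- switch(mass_average,
    number = function(x) {
      p <- x^(n - 1)
      sum(n * p) / sum(p)
    },
    weight = function(x) {
      p <- x^(n - 1)
      sum(n^2 * p) / sum(n * p)
    })
  f <- function(x) ratio(x) - r
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  root <- stats::uniroot(f, c(1e-12, hi), tol = .Machine$double.eps^0.75)
  x <- root$root
  p <- x^(n - 1)
  m <- ctot / sum(n * p)
  conc <- m * p
  kd <- m / x

  navg <- m1 * sum(n * conc) / sum(conc)
  resid <- abs(switch(mass_average,
    number = navg,
    weight = m1 * sum(n^2 * conc) / sum(n * conc)) -
    observed_avg_mass) / observed_avg_mass
  if (resid > 1e-8)
    stop(sprintf("isodesmic solve did not converge: relative residual %.3g",
                 resid))

  dist <- structure(
    list(concentrations = conc,
         number_average_mass = navg,
         protomer_sum = sum(n * conc)),
    class = "species_distribution")
  est <- structure(
    list(kd = kd,
         max_order = N,
         residual = resid,
         monomer_fraction_of_protomers = m / ctot),
    class = "kd_estimate")
  list(distribution = dist, kd = est)
}

#' Define an isodesmic oligomerization problem
#'
#' @param total_protomer_conc total concentration of protomers across all
#'   species, in nM.
#' @param monomer_mass protomer mass in kDa.
#' @param max_order largest oligomer size included in the truncated series.
#' @return An `isodesmic_system` list.
#' @export
isodesmic_system <- function(total_protomer_conc, monomer_mass, max_order) {
  stopifnot(is.numeric(total_protomer_conc), length(total_protomer_conc) == 1L,
            is.numeric(monomer_mass), length(monomer_mass) == 1L,
            is.numeric(max_order), length(max_order) == 1L)
  if (!is.finite(total_protomer_conc) || total_protomer_conc <= 0)
    stop("total_protomer_conc must be > 0")
  if (!is.finite(monomer_mass) || monomer_mass <= 0)
    stop("monomer_mass must be > 0")
  if (max_order < 1 || max_order != round(max_order))
    stop("max_order must be an integer >= 1")
  structure(list(total_protomer_conc = total_protomer_conc,
                 monomer_mass = monomer_mass,
                 max_order = as.integer(max_order)),
            class = "isodesmic_system")
}

#' Number-average mass implied by an isodesmic dissociation constant
#'
#' Forward model inverting [solve_isodesmic()]: given K and the total
#' protomer concentration, solve conservation for the monomer
#' concentration and return the number-average species mass of the
#' truncated isodesmic distribution.
#'
#' @param kd stepwise dissociation constant in nM.
#' @param total_protomer_conc total protomer concentration in nM.
#' @param monomer_mass protomer mass in kDa.
#' @param max_order truncation order N.
#' @return Number-average mass in kDa.
#' @export
predict_average_mass <- function(kd, total_protomer_conc, monomer_mass,
                                 max_order) {
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("kd must be a single positive number")
  if (!is.finite(total_protomer_conc) || total_protomer_conc <= 0)
    stop("total_protomer_conc must be > 0")
  if (!is.finite(monomer_mass) || monomer_mass <= 0)
    stop("monomer_mass must be > 0")
  if (max_order < 1 || max_order != round(max_order))
    stop("max_order must be an integer >= 1")
  N <- as.integer(max_order)
  if (N == 1L) return(monomer_mass)
  n <- seq_len(N)
  # conservation: kd * sum(n x^n) = c_tot, increasing in x
  g <- function(x) kd * sum(n * x^n) - total_protomer_conc
  hi <- 1
  while (g(hi) < 0) hi <- hi * 2
  x <- stats::uniroot(g, c(0, hi), tol = .Machine$double.eps^0.75)$root
  p <- x^(n - 1)
  monomer_mass * sum(n * p) / sum(p)
}

#' Dissociation constant in the infinite-series limit
#'
#' As the truncation order grows, the isodesmic series converges (for
#' monomer fraction x = m/K < 1) so that
#' \eqn{M_{avg}/M_1 = 1/(1-x)}; hence \eqn{x = 1 - M_1/M_{avg}} and
#' \eqn{K = c_{tot} (1-x)^2 / x}.
#'
#' @param observed_avg_mass number-average mass in kDa.
#' @param monomer_mass protomer mass in kDa.
#' @param total_protomer_conc total protomer concentration in nM.
#' @return Limiting dissociation constant in nM.
#' @export
infinite_limit_kd <- function(observed_avg_mass, monomer_mass,
                              total_protomer_conc) {
  if (!is.finite(monomer_mass) || monomer_mass <= 0)
    stop("monomer_mass must be > 0")
  if (!is.finite(total_protomer_conc) || total_protomer_conc <= 0)
    stop("total_protomer_conc must be > 0")
  if (!is.finite(observed_avg_mass) || observed_avg_mass <= monomer_mass)
    stop("observed_avg_mass must exceed the monomer mass")
  x <- 1 - monomer_mass / observed_avg_mass
  total_protomer_conc * (1 - x)^2 / x
}

#' Dissociation constant as a function of the truncation order
#'
#' Solves the isodesmic system once per truncation order, showing how the
#' inferred K converges as higher-order oligomers are admitted.
#'
#' @param total_protomer_conc total protomer concentration in nM.
#' @param monomer_mass protomer mass in kDa.
#' @param observed_avg_mass measured number-average mass in kDa.
#' @param orders integer vector of truncation orders (each >= 2),
#'   ascending.
#' @return A data.frame with columns `max_order` and `kd_nM`.
#' @export
convergence_table <- function(total_protomer_conc, monomer_mass,
                              observed_avg_mass, orders) {
  if (length(orders) < 1L || any(orders < 2) ||
      any(orders != round(orders)))
    stop("orders must be integers >= 2")
  if (is.unsorted(orders, strictly = TRUE))
    stop("orders must be strictly ascending")
  kd <- vapply(orders, function(N) {
    fit <- tryCatch(
      solve_isodesmic(isodesmic_system(total_protomer_conc, monomer_mass, N),
                      observed_avg_mass),
      error = function(e) stop(sprintf("order %d: %s", N, conditionMessage(e)),
                               call. = FALSE))
    fit$kd$kd
  }, numeric(1))
  data.frame(max_order = as.integer(orders), kd_nM = kd)
}

#' Average protomers per oligomer
#'
#' Converts a measured absolute (average) mass into protomers per
#' oligomer by dividing by the protomer mass.
#'
#' @param average_mass measured average oligomer mass in kDa.
#' @param monomer_mass protomer mass in kDa.
#' @return Dimensionless protomers per oligomer.
#' @export
oligomer_count <- function(average_mass, monomer_mass) {
  if (any(!is.finite(average_mass)) || any(average_mass <= 0))
    stop("average_mass must be > 0")
  if (!is.finite(monomer_mass) || monomer_mass <= 0)
    stop("monomer_mass must be > 0")
  average_mass / monomer_mass
}

#' A SEC-MALS concentration/mass series
#'
#' @param detector_conc_uM concentration at the detector, in uM.
#' @param average_mass_kDa absolute (average) mass at that concentration,
#'   in kDa.
#' @param injected_conc_uM optional injected concentrations, in uM.
#' @return A `mals_series` data.frame.
#' @export
mals_series <- function(detector_conc_uM, average_mass_kDa,
                        injected_conc_uM = NULL) {
  stopifnot(length(detector_conc_uM) == length(average_mass_kDa))
  if (length(detector_conc_uM) < 1L) stop("series must have at least one row")
  if (any(!is.finite(detector_conc_uM)) || any(detector_conc_uM <= 0) ||
      any(!is.finite(average_mass_kDa)) || any(average_mass_kDa <= 0))
    stop("all series entries must be positive and finite")
  if (anyDuplicated(detector_conc_uM))
    stop("detector concentrations must be unique")
  out <- data.frame(detector_conc_uM = detector_conc_uM,
                    average_mass_kDa = average_mass_kDa)
  if (!is.null(injected_conc_uM)) out$injected_conc_uM <- injected_conc_uM
  class(out) <- c("mals_series", class(out))
  out
}

#' Fit a dissociation constant to a MALS concentration series
#'
#' Least-squares fit of the isodesmic forward model
#' [predict_average_mass()] to a series of (detector concentration,
#' average mass) measurements. Concentrations are converted from uM to nM
#' internally; K is optimized on a log scale by golden-section search.
#'
#' @param series a [mals_series()].
#' @param monomer_mass protomer mass in kDa.
#' @param max_order truncation order N.
#' @return A `kd_estimate` (residual holds the root-mean-square mass
#'   residual in kDa; `monomer_fraction_of_protomers` refers to the first
#'   series row).
#' @export
fit_kd_to_series <- function(series, monomer_mass, max_order) {
  stopifnot(inherits(series, "mals_series"))
  conc_nM <- series$detector_conc_uM * 1e3
  mass <- series$average_mass_kDa
  feasible <- mass > monomer_mass & mass < monomer_mass * max_order
  if (!any(feasible))
    stop("all series rows are infeasible for this monomer mass and order")
  sse <- function(logk) {
    pred <- vapply(conc_nM, function(ct)
      predict_average_mass(exp(logk), ct, monomer_mass, max_order),
      numeric(1))
    sum((pred - mass)^2)
  }
  opt <- stats::optimize(sse, c(log(1e-4), log(1e10)), tol = 1e-12)
  kd <- exp(opt$minimum)
  dist1 <- solve_isodesmic(
    isodesmic_system(conc_nM[1], monomer_mass, max_order),
    predict_average_mass(kd, conc_nM[1], monomer_mass, max_order))
  structure(
    list(kd = kd,
         max_order = as.integer(max_order),
         residual = sqrt(opt$objective / length(mass)),
         monomer_fraction_of_protomers =
           dist1$kd$monomer_fraction_of_protomers),
    class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf(
    "Isodesmic K_D estimate: %.4g nM (truncation order %d)\n", x$kd,
    x$max_order))
  cat(sprintf("  residual %.3g, monomer fraction of protomers %.3f\n",
              x$residual, x$monomer_fraction_of_protomers))
  invisible(x)
}

#' @export
print.species_distribution <- function(x, ...) {
  cat(sprintf(
    "Isodesmic species distribution (N = %d): number-average mass %.4g kDa, protomer sum %.6g nM\n",
    length(x$concentrations), x$number_average_mass, x$protomer_sum))
  print(round(x$concentrations, 3))
  invisible(x)
}
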
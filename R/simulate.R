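#' Configuration for a synthetic TIRF movie
#'
#' Defaults emulate the live-cell imaging conditions the pipeline is
#' meant for: a 512 x 512 field, 40 frames at 100 ms exposure, 150
#' diffraction-limited spots with a Gaussian PSF of 1 px, copy numbers
#' drawn from an explicit probability vector over 1..12, 120 counts of
#' integrated intensity per fluorophore, per-fluorophore single-
#' exponential photobleaching at 0.02/frame, a 10% linear background
#' gradient over the field, Poisson shot noise plus Gaussian read noise,
#' and slow spot motion (0.05 px/frame random walk).
#'
#' @param size image side length in pixels.
#' @param n_spots number of spots.
#' @param copy_probs probability vector over copy numbers 1..length;
#'   must sum to 1.
#' @param g integrated intensity per fluorophore, counts.
#' @param psf_sigma PSF standard deviation, pixels.
#' @param background mean background level, counts.
#' @param background_gradient fractional peak-to-peak linear ramp of the
#'   background across columns.
#' @param shot_noise apply Poisson shot noise (logical).
#' @param read_noise_sd Gaussian read noise standard deviation, counts.
#' @param bleach_rate per-fluorophore bleaching rate per frame; each
#'   fluorophore independently survives a frame step with probability
#'   exp(-bleach_rate).
#' @param diffusion_sd random-walk step standard deviation, px/frame.
#' @param frames number of frames.
#' @param pixel_size_nm,exposure_ms stack metadata.
#' @param seed integer seed.
#' @return A `tirf_sim_config` list.
#' @export
tirf_sim_config <- function(size = 512L, n_spots = 150L,
                            copy_probs = c(0.30, 0.20, 0.14, 0.10, 0.07,
                                           0.05, 0.04, 0.03, 0.025, 0.02,
                                           0.015, 0.01),
                            g = 120, psf_sigma = 1.0,
                            background = 50, background_gradient = 0.1,
                            shot_noise = TRUE, read_noise_sd = 3,
                            bleach_rate = 0.02, diffusion_sd = 0.05,
                            frames = 40L, pixel_size_nm = 65,
                            exposure_ms = 100, seed = 1L) {
  if (abs(sum(copy_probs) - 1) > 1e-8 || any(copy_probs < 0))
    stop("copy_probs must be non-negative and sum to 1")
  if (frames < 1) stop("frames must be >= 1")
  if (any(c(g, psf_sigma) <= 0)) stop("g and psf_sigma must be > 0")
  if (any(c(background, read_noise_sd, bleach_rate, diffusion_sd) < 0))
    stop("rates and noise levels must be >= 0")
  if (n_spots < 0 || size < 16) stop("invalid geometry")
  structure(as.list(environment()), class = "tirf_sim_config")
}

# pixel-integrated Gaussian PSF: fraction of a unit-flux fluorophore at
# (x0, y0) landing in each pixel of the rows x cols window (0-based
# pixel-centre convention; pixel j spans [j - 0.5, j + 0.5])
psf_patch <- function(x0, y0, rows, cols, sigma) {
  fx <- stats::pnorm(cols + 0.5, x0, sigma) -
    stats::pnorm(cols - 0.5, x0, sigma)
  fy <- stats::pnorm(rows + 0.5, y0, sigma) -
    stats::pnorm(rows - 0.5, y0, sigma)
  outer(fy, fx)
}

#' Simulate a TIRF movie with known per-spot fluorophore counts
#'
#' Each spot carries n fluorophores drawn from `copy_probs`; all are
#' alive in frame 1 and each independently survives every subsequent
#' frame step with probability exp(-bleach_rate). The noise-free frame is
#' background (with its linear gradient) plus, per spot, the surviving
#' fluorophore count times g times a pixel-integrated Gaussian PSF, so
#' one unbleached fluorophore integrates to exactly g counts. Poisson
#' shot noise is applied to the full expected image, then Gaussian read
#' noise is added. Spot centres follow seeded Gaussian random walks.
#'
#' @param config a [tirf_sim_config()].
#' @return List with `stack` (an [image_stack()]), and `truth`: `spots`
#'   (spot id, copy number n, initial position), `per_frame` (spot,
#'   frame, x, y, surviving fluorophores, expected integrated intensity),
#'   and `signal_sum` (total noise-free signal added per frame, counts).
#' @export
simulate_tirf_stack <- function(config) {
  stopifnot(inherits(config, "tirf_sim_config"))
  cf <- config
  with_seed(cf$seed, {
    sz <- cf$size
    n_max <- length(cf$copy_probs)
    margin <- ceiling(6 * cf$psf_sigma) + 2
    spots <- data.frame(
      spot = seq_len(cf$n_spots),
      n = if (cf$n_spots > 0)
        sample.int(n_max, cf$n_spots, replace = TRUE, prob = cf$copy_probs)
      else integer(0),
      x0 = stats::runif(cf$n_spots, margin, sz - 1 - margin),
      y0 = stats::runif(cf$n_spots, margin, sz - 1 - margin))

    ramp <- cf$background *
      (1 + cf$background_gradient * ((0:(sz - 1)) / (sz - 1) - 0.5))
    bg <- matrix(rep(ramp, each = sz), sz, sz)

    arr <- array(0, c(cf$frames, sz, sz))
    pf <- vector("list", cf$frames)
    signal_sum <- numeric(cf$frames)
    x <- spots$x0; y <- spots$y0
    alive <- spots$n
    surv_p <- exp(-cf$bleach_rate)
    rad <- ceiling(6 * cf$psf_sigma)
    for (f in seq_len(cf$frames)) {
      if (f > 1) {
        x <- x + stats::rnorm(cf$n_spots, 0, cf$diffusion_sd)
        y <- y + stats::rnorm(cf$n_spots, 0, cf$diffusion_sd)
        alive <- stats::rbinom(cf$n_spots, alive, surv_p)
      }
      frame <- bg
      for (s in seq_len(cf$n_spots)) {
        if (alive[s] == 0) next
        rows <- max(0, round(y[s]) - rad):min(sz - 1, round(y[s]) + rad)
        cols <- max(0, round(x[s]) - rad):min(sz - 1, round(x[s]) + rad)
        patch <- psf_patch(x[s], y[s], rows, cols, cf$psf_sigma)
        add <- cf$g * alive[s] * patch
        frame[rows + 1, cols + 1] <- frame[rows + 1, cols + 1] + add
        signal_sum[f] <- signal_sum[f] + sum(add)
      }
      if (cf$shot_noise)
        frame <- matrix(stats::rpois(sz * sz, frame), sz, sz)
      if (cf$read_noise_sd > 0)
        frame <- frame + matrix(stats::rnorm(sz * sz, 0, cf$read_noise_sd),
                                sz, sz)
      arr[f, , ] <- pmax(frame, 0)
      pf[[f]] <- data.frame(spot = spots$spot, frame = rep(f, cf$n_spots),
                            x = x, y = y,
                            surviving = alive,
                            intensity = cf$g * alive)
    }
    list(stack = image_stack(arr, cf$pixel_size_nm, cf$exposure_ms),
         truth = list(spots = spots,
                      per_frame = do.call(rbind, pf),
                      signal_sum = signal_sum))
  })
}

#' Simulate a SEC-MALS concentration/mass series
#'
#' Forward model of a dilution series: the number-average mass at each
#' detector concentration follows the truncated isodesmic model with the
#' given ground-truth K, multiplied by lognormal noise with the given
#' fractional standard deviation (sdlog = `noise_sd_frac`, meanlog 0).
#'
#' @param kd ground-truth stepwise dissociation constant, nM.
#' @param monomer_mass protomer mass, kDa.
#' @param detector_concs_uM detector concentrations, uM.
#' @param noise_sd_frac fractional lognormal mass noise (0 = noiseless).
#' @param max_order truncation order of the forward model.
#' @param seed integer seed (optional).
#' @return A [mals_series()].
#' @export
simulate_mals_series <- function(kd, monomer_mass, detector_concs_uM,
                                 noise_sd_frac = 0, max_order = 11,
                                 seed = NULL) {
  if (!is.finite(kd) || kd <= 0) stop("kd must be > 0")
  mass <- vapply(detector_concs_uM, function(cu)
    predict_average_mass(kd, cu * 1e3, monomer_mass, max_order),
    numeric(1))
  if (noise_sd_frac > 0)
    mass <- with_seed(seed,
      mass * exp(stats::rnorm(length(mass), 0, noise_sd_frac)))
  mals_series(detector_concs_uM, mass)
}

#' Simulate per-field mean-gray-value sets with a known effect
#'
#' Group A ~ Normal(baseline * (1 + effect_frac), noise_sd); group B ~
#' Normal(baseline, noise_sd). Emulates field-level fluorescence
#' comparisons between a treated and a control condition.
#'
#' @param n_fields_a,n_fields_b fields per group (>= 1).
#' @param baseline mean gray value of the control condition.
#' @param effect_frac fractional mean increase in group A.
#' @param noise_sd field-to-field standard deviation, same units as
#'   `baseline`.
#' @param seed integer seed (optional).
#' @return List with numeric vectors `a` and `b`.
#' @export
simulate_mgv_fields <- function(n_fields_a, n_fields_b, baseline = 100,
                                effect_frac = 0.15, noise_sd = 5,
                                seed = NULL) {
  if (n_fields_a < 1 || n_fields_b < 1) stop("each group needs >= 1 field")
  with_seed(seed, list(
    a = stats::rnorm(n_fields_a, baseline * (1 + effect_frac), noise_sd),
    b = stats::rnorm(n_fields_b, baseline, noise_sd)))
}
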
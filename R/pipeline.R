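#' Run the full single-molecule copy-number pipeline on a movie
#'
#' Chains the TIRF stages with the standard settings: rolling-ball
#' background subtraction (5 px ball), rolling-window time averaging
#' (window 5), spot detection (alpha 0.05, PSF sigma 1 px), trajectory
#' linking (maximum closed gap 4 frames), selection of trajectories at
#' least 10 detected frames long, integrated start-frame intensities,
#' Gaussian-mixture fitting with information-criterion model selection
#' (100 replicates, 500 iterations), single-fluorophore calibration from
#' the two smallest component means, and the fraction of normalized spot
#' intensities within `multiple` of one fluorophore.
#'
#' @param stack an [image_stack()] movie.
#' @param alpha detection significance level.
#' @param psf_sigma_px PSF standard deviation, pixels.
#' @param rolling_ball_diameter background ball diameter, pixels.
#' @param time_window time-averaging window, frames.
#' @param max_gap maximum trajectory gap to close, frames.
#' @param max_disp_px frame-to-frame displacement gate, pixels.
#' @param min_length minimum trajectory length, detected frames.
#' @param k_max largest mixture size tried.
#' @param criterion `"BIC"` or `"AIC"`.
#' @param replicates,max_iter mixture fit settings.
#' @param multiple copy-number multiple for the summary fraction.
#' @param seed integer seed driving the mixture-fit initializations.
#' @return A `tirf_report` list: `detections` (data.frame), `n_spots`
#'   per frame, `trajectories` (list), `intensities` (start samples),
#'   `gmm`, `calibration`, `normalized`, `fraction_within`, and a
#'   `provenance` record of all parameters and the seed.
#' @export
tirf_pipeline <- function(stack, alpha = 0.05, psf_sigma_px = 1.0,
                          rolling_ball_diameter = 5, time_window = 5,
                          max_gap = 4, max_disp_px = 2, min_length = 10,
                          k_max = 8, criterion = "BIC", replicates = 100,
                          max_iter = 500, multiple = 10, seed = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  params <- list(alpha = alpha, psf_sigma_px = psf_sigma_px,
                 rolling_ball_diameter = rolling_ball_diameter,
                 time_window = time_window, max_gap = max_gap,
                 max_disp_px = max_disp_px, min_length = min_length,
                 k_max = k_max, criterion = criterion,
                 replicates = replicates, max_iter = max_iter,
                 multiple = multiple)
  pre <- rolling_ball_subtract(stack, rolling_ball_diameter)
  pre <- time_average(pre, time_window)
  detections <- detect_spots_stack(pre, alpha, psf_sigma_px)
  trajectories <- link_trajectories(detections, max_gap, max_disp_px)
  trajectories <- select_trajectories(trajectories, min_length)
  if (length(trajectories) == 0)
    stop("no trajectories of the required length; nothing to calibrate")
  intensities <- start_intensities(trajectories)
  gmm <- select_gmm(intensities, k_max, criterion, replicates, max_iter,
                    seed = seed)
  cal <- calibrate(gmm)
  normalized <- normalize_intensities(cal, intensities)
  structure(
    list(detections = detections,
         n_spots = as.vector(table(factor(detections$frame,
                                          levels = seq_len(dim(stack$data)[1])))),
         trajectories = trajectories,
         intensities = intensities,
         gmm = gmm,
         calibration = cal,
         normalized = normalized,
         fraction_within = fraction_within(normalized, multiple),
         provenance = provenance_record("tirf_pipeline", params, seed)),
    class = "tirf_report")
}

#' @export
print.tirf_report <- function(x, ...) {
  cat(sprintf(
    paste0("TIRF copy-number report: %d detections, %d trajectories ",
           ">= %d frames\n"),
    nrow(x$detections), length(x$trajectories),
    x$provenance$parameters$min_length))
  cat(sprintf(
    "  mixture k = %d (%s); g = %.2f counts, background offset b = %.2f\n",
    x$gmm$k, x$gmm$criterion, x$calibration$single_fluor_intensity,
    x$calibration$background))
  cat(sprintf(
    "  fraction of spots within %gx of a single fluorophore: %.3f\n",
    x$provenance$parameters$multiple, x$fraction_within))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the scalar results, per-trajectory intensities and provenance
#' (not the raw detections) as JSON; two runs with the same stack and
#' seed produce byte-identical files.
#'
#' @param report a [tirf_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tirf_report <- function(report, path) {
  stopifnot(inherits(report, "tirf_report"))
  out <- list(
    n_detections = nrow(report$detections),
    n_trajectories = length(report$trajectories),
    intensities = report$intensities,
    gmm = report$gmm[c("k", "means", "variances", "weights", "loglik",
                       "bic", "aic", "criterion")],
    single_fluor_intensity = report$calibration$single_fluor_intensity,
    background = report$calibration$background,
    fraction_within = report$fraction_within,
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
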
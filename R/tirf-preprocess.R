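# disc of pixel offsets with Euclidean distance <= diameter/2
disc_offsets <- function(diameter) {
  r <- diameter / 2
  ri <- floor(r)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g[sqrt(g$dy^2 + g$dx^2) <= r + 1e-9, , drop = FALSE]
}

# sliding min (op = pmin) or max (op = pmax) over a set of offsets;
# out-of-bounds pixels are ignored (identity element padding)
shift_filter <- function(mat, offsets, op, pad) {
  nr <- nrow(mat); nc <- ncol(mat)
  acc <- matrix(pad, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    dy <- offsets$dy[k]; dx <- offsets$dx[k]
    sr <- max(1, 1 - dy):min(nr, nr - dy)
    sc <- max(1, 1 - dx):min(nc, nc - dx)
    acc[sr, sc] <- op(acc[sr, sc], mat[sr + dy, sc + dx])
  }
  acc
}

grayscale_opening <- function(mat, offsets) {
  eroded <- shift_filter(mat, offsets, pmin, Inf)
  shift_filter(eroded, offsets, pmax, -Inf)
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of each frame by grayscale
#' morphological opening with a disc structuring element (the flat
#' approximation of a rolling ball of the given diameter) and subtracts
#' it. Features narrower than the disc -- diffraction-limited spots --
#' survive; smooth background, including gradients, is removed. Output is
#' clamped at zero.
#'
#' @param stack an [image_stack()].
#' @param diameter_px ball diameter in pixels (default 5).
#' @return A background-subtracted [image_stack()].
#' @export
rolling_ball_subtract <- function(stack, diameter_px = 5) {
  stopifnot(inherits(stack, "image_stack"))
  if (diameter_px < 1) stop("diameter_px must be >= 1")
  d <- dim(stack$data)
  if (diameter_px > min(d[2], d[3]))
    stop("ball diameter exceeds the image size")
  off <- disc_offsets(diameter_px)
  out <- stack$data
  for (f in seq_len(d[1])) {
    frame <- stack$data[f, , ]
    out[f, , ] <- pmax(frame - grayscale_opening(frame, off), 0)
  }
  stack$data <- out
  stack
}

#' Rolling-window time averaging
#'
#' Replaces frame t by the mean over a centered window of `window`
#' frames, truncated at the stack edges. Reduces shot noise by roughly
#' sqrt(window) for spots that move little within the window.
#'
#' @param stack an [image_stack()].
#' @param window odd window size in frames (default 5); `window = 1` is
#'   the identity.
#' @return A time-averaged [image_stack()].
#' @export
time_average <- function(stack, window = 5) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- dim(stack$data)[1]
  if (window < 1 || window != round(window)) stop("window must be an integer >= 1")
  if (window > nf) stop("window exceeds the number of frames")
  if (window == 1) return(stack)
  half <- floor(window / 2)
  out <- stack$data
  for (t in seq_len(nf)) {
    idx <- max(1, t - half):min(nf, t + half)
    out[t, , ] <- colMeans(stack$data[idx, , , drop = FALSE], dims = 1)
  }
  stack$data <- out
  stack
}

#' Mean gray values of a set of fields
#'
#' @param fields list of 2-D numeric matrices (one per field of view).
#' @param crop optional integer c(rows, cols): use only a centered crop
#'   of that size from each field.
#' @return Numeric vector of per-field means.
#' @export
mean_gray_values <- function(fields, crop = NULL) {
  if (!is.list(fields) || length(fields) < 1L)
    stop("fields must be a non-empty list of matrices")
  vapply(fields, function(f) {
    if (!is.matrix(f)) stop("each field must be a matrix")
    if (!is.null(crop)) {
      if (length(crop) != 2L || any(crop < 1))
        stop("crop must be c(rows, cols)")
      if (crop[1] > nrow(f) || crop[2] > ncol(f))
        stop("crop exceeds the field size")
      r0 <- floor((nrow(f) - crop[1]) / 2)
      c0 <- floor((ncol(f) - crop[2]) / 2)
      f <- f[r0 + seq_len(crop[1]), c0 + seq_len(crop[2])]
    }
    mean(f)
  }, numeric(1))
}
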
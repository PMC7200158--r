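#' A fluorescence movie as a frames x rows x cols array
#'
#' @param data numeric array with dim (frames, rows, cols), all finite
#'   and non-negative; a single matrix is promoted to one frame.
#' @param pixel_size_nm physical pixel size in nm.
#' @param exposure_ms exposure per frame in ms.
#' @return An `image_stack`.
#' @export
image_stack <- function(data, pixel_size_nm = 65, exposure_ms = 100) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a (frames, rows, cols) array")
  if (dim(data)[1] < 1L) stop("stack needs at least one frame")
  if (any(!is.finite(data))) stop("stack contains non-finite values")
  structure(list(data = data,
                 pixel_size_nm = pixel_size_nm,
                 exposure_ms = exposure_ms),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_stack: %d frame(s) of %d x %d px (%.3g nm/px, %.3g ms/frame)\n",
    d[1], d[2], d[3], x$pixel_size_nm, x$exposure_ms))
  invisible(x)
}

#' Read a multi-frame TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param pixel_size_nm,exposure_ms metadata attached to the stack (plain
#'   TIFF does not carry them).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size_nm = 65, exposure_ms = 100) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (is.list(info) && !is.data.frame(info)) info <- info[[1]]
  scaled32 <- isTRUE(info$bits.per.sample[1] == 32)
  frames <- tiff::readTIFF(path, all = TRUE, as.is = !scaled32)
  if (scaled32) frames <- lapply(
    if (is.list(frames)) frames else list(frames),
    function(m) m * 65536)
  if (!is.list(frames)) frames <- list(frames)
  d <- dim(frames[[1]])
  arr <- array(0, c(length(frames), d[1], d[2]))
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d))
      stop(sprintf("frame %d has inconsistent dimensions", i))
    arr[i, , ] <- frames[[i]]
  }
  image_stack(arr, pixel_size_nm, exposure_ms)
}

#' Write an image stack to a multi-frame TIFF
#'
#' Integer-valued stacks within \[0, 65535\] are written as 16-bit
#' (bit-exact round trip); other stacks must lie in \[0, 65536) and are
#' written as 32-bit samples scaled by 1/65536, giving an absolute
#' round-trip precision of about 1.5e-5 counts.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  x <- stack$data
  frames <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
  int_ok <- all(x >= 0 & x <= 65535 & x == round(x))
  if (int_ok) {
    tiff::writeTIFF(lapply(frames, function(m) m / 65535), path,
                    bits.per.sample = 16)
  } else {
    if (any(x < 0) || any(x >= 65536))
      stop("non-integer stacks must lie in [0, 65536) for TIFF export")
    tiff::writeTIFF(lapply(frames, function(m) m / 65536), path,
                    bits.per.sample = 32, reduce = FALSE)
  }
  invisible(path)
}

#' Write a data.frame as CSV (9 significant digits, header mandatory)
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], signif, digits = 9)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path file path.
#' @return A data.frame.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, check.names = FALSE)
}

#' Derive a deterministic per-stage child seed from a global seed
#'
#' Lets one run seed drive every stochastic stage while keeping the
#' stages' streams distinct and reproducible.
#'
#' @param seed global integer seed.
#' @param stage character stage label.
#' @return An integer seed in \[0, 2^31).
#' @export
child_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Machine-readable provenance record for a pipeline run
#'
#' @param stage character label of the analysis stage.
#' @param params named list of parameters.
#' @param seed the seed used (or NULL).
#' @return A list with stage, parameters, seed and package version.
#' @export
provenance_record <- function(stage, params, seed = NULL) {
  list(stage = stage,
       parameters = params,
       seed = seed,
       package = "oligocount",
       version = as.character(utils::packageVersion("oligocount")))
}
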
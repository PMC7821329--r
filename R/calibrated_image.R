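#' Calibrated fluorescence image
#'
#' A 2-D intensity array (arbitrary units, AU) together with its physical
#' pixel size. All physical quantities in the package are expressed in
#' micrometres (um), seconds (s) and AU; the calibration attached here is the
#' substrate of every downstream measurement.
#'
#' Coordinate convention: `pixels[row, col]`, with the x axis running along
#' columns and the y axis along rows; the centre of pixel `[r, c]` sits at
#' physical position `((c - 0.5) * pixel_size, (r - 0.5) * pixel_size)` um.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities (AU).
#' @param pixel_size Physical size of one pixel in um; must be > 0.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (any(pixels < 0))
    stop("image intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/pixel)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px @ %.4g um/px, range [%.4g, %.4g] AU\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Time-lapse image stack
#'
#' An ordered list of equally calibrated frames acquired at a fixed frame
#' interval, e.g. a TIRF time lapse used for single-particle tracking.
#'
#' @param frames List of numeric matrices with identical dimensions, or a list
#'   of `calibrated_image` objects with identical calibration.
#' @param pixel_size um per pixel (ignored when `frames` are already
#'   calibrated).
#' @param frame_interval Time between consecutive frames in s; must be > 0.
#' @return An object of class `image_stack` with fields `frames` (list of
#'   matrices), `pixel_size` and `frame_interval`.
#' @export
image_stack <- function(frames, pixel_size = NULL, frame_interval) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list")
  if (inherits(frames[[1]], "calibrated_image")) {
    ps <- unique(vapply(frames, function(f) f$pixel_size, numeric(1)))
    if (length(ps) != 1L) stop("frames differ in pixel_size")
    pixel_size <- ps
    frames <- lapply(frames, `[[`, "pixels")
  }
  if (is.null(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/pixel)")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same dimensions")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("`frame_interval` must be a single positive number (s)")
  structure(list(frames = frames, pixel_size = as.numeric(pixel_size),
                 frame_interval = as.numeric(frame_interval)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frames of %d x %d px @ %.4g um/px, dt = %.4g s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param x An `image_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  length(x$frames)
}
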
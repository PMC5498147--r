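#' Construct a frame stack
#'
#' A frame stack holds one specimen's multi-channel z-stack acquired at one
#' time point, together with the lateral pixel size and the acquisition time.
#'
#' @param intensities numeric array indexed `[channel, z, row, col]`;
#'   non-negative intensities. A plain matrix is promoted to a single-channel,
#'   single-plane stack.
#' @param pixel_size lateral pixel size in micrometres per pixel (> 0).
#' @param time_index integer acquisition index (>= 0).
#' @param time_h acquisition time in hours (>= 0).
#' @param specimen_id identifier of the specimen (position) this stack images.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(intensities, pixel_size, time_index = 0L,
                        time_h = 0, specimen_id = "s1") {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, dim = c(1L, 1L, dim(intensities)))
  }
  if (!is.array(intensities) || length(dim(intensities)) != 4L)
    stop("intensities must be a [channel, z, row, col] array or a matrix")
  if (any(dim(intensities) < 1L)) stop("all four stack dimensions must be >= 1")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be finite and > 0")
  if (time_index < 0) stop("time_index must be >= 0")
  if (time_h < 0) stop("time_h must be >= 0")
  structure(
    list(intensities = intensities, pixel_size = as.numeric(pixel_size),
         time_index = as.integer(time_index), time_h = as.numeric(time_h),
         specimen_id = as.character(specimen_id)),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<frame_stack> specimen %s, t=%d (%.2f h), %d channel(s) x %d z x %d x %d px @ %.3f um/px\n",
    x$specimen_id, x$time_index, x$time_h, d[1], d[2], d[3], d[4], x$pixel_size))
  invisible(x)
}

#' Maximum intensity projection of one channel
#'
#' Collapses the z dimension of a stack by taking the per-pixel maximum,
#' the projection used by the tracker to reduce a z-stack to a 2-D image.
#'
#' @param stack a [frame_stack].
#' @param channel 1-based channel index.
#' @return numeric matrix `[row, col]` of per-pixel maxima over z.
#' @export
max_intensity_project <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$intensities)
  if (channel < 1L || channel > d[1])
    stop(sprintf("invalid channel index %d: stack has %d channel(s)",
                 channel, d[1]))
  # collapse z by running pmax over planes (fast for large frames)
  proj <- matrix(stack$intensities[channel, 1L, , ], d[3], d[4])
  if (d[2] > 1L) for (z in 2L:d[2]) {
    proj <- pmax(proj, matrix(stack$intensities[channel, z, , ], d[3], d[4]))
  }
  proj
}
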
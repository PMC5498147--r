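#' Rotation-stage calibration
#'
#' Holds the stage coordinates (micrometres) of the mechanical centre of
#' rotation of the sample chamber, established once by imaging a small
#' drilled hole that coincides with the rotation axis.
#'
#' @param centre_x_um,centre_y_um stage coordinates of the rotation centre.
#' @return a `rotation_calibration` object.
#' @export
rotation_calibration <- function(centre_x_um, centre_y_um) {
  stopifnot(is.finite(centre_x_um), is.finite(centre_y_um))
  structure(list(centre_x_um = as.numeric(centre_x_um),
                 centre_y_um = as.numeric(centre_y_um)),
            class = "rotation_calibration")
}

#' Locate the calibration hole in a frame
#'
#' Finds the single bright disk-like region (the drilled calibration hole)
#' in an image acquired at a known stage position and returns the stage
#' coordinates of its intensity centroid: segmentation by Otsu threshold,
#' connected-component labelling, then
#' `stage + (centroid - frame centre) * pixel_size` under the axis map.
#'
#' @param image numeric matrix (2-D frame, e.g. a projection).
#' @param pixel_size micrometres per pixel.
#' @param stage_pos single-row stage-position data frame (or a list with
#'   `x_um`, `y_um`) at which the image was acquired.
#' @param axis_map an [axis_map].
#' @param min_area_px smallest connected component regarded as a candidate
#'   disk (suppresses isolated noise pixels).
#' @return a [rotation_calibration].
#' @export
locate_calibration_hole <- function(image, pixel_size, stage_pos,
                                    axis_map = tiptrace::axis_map(),
                                    min_area_px = 9L) {
  if (!is.matrix(image)) stop("image must be a matrix")
  rng <- range(image)
  if (diff(rng) == 0) stop("found 0 candidate disks: image has no contrast")
  norm <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(round(EBImage::imageData(labels)))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (length(keep) != 1)
    stop("found ", length(keep), " candidate disks, expected exactly 1")
  sel <- lab == keep
  w <- image * sel
  # intensity-weighted centroid in 0-based pixel coordinates
  rows <- row(image) - 1
  cols <- col(image) - 1
  cr <- sum(rows * w) / sum(w)
  cc <- sum(cols * w) / sum(w)
  centre <- c((ncol(image) - 1) / 2, (nrow(image) - 1) / 2)  # (col, row)
  off <- apply_axis_map((c(cc, cr) - centre) * pixel_size, axis_map)
  rotation_calibration(centre_x_um = stage_pos$x_um[1] + off[1],
                       centre_y_um = stage_pos$y_um[1] + off[2])
}

#' Recompute stage positions after rotating the sample chamber
#'
#' Maps each position P to `C + R(angle) (P - C)` where C is the calibrated
#' centre of rotation. Positive angles are clockwise as seen in the
#' displayed image; with the row-down image convention this is the
#' mathematically positive rotation in (x, y-down) stage coordinates, so
#' `R = [[cos, -sin], [sin, cos]]`. z and activity are unchanged and the
#' specimen order is preserved.
#'
#' @param positions stage-position data frame.
#' @param calib a [rotation_calibration].
#' @param angle_deg rotation angle in degrees, clockwise positive.
#' @return the rotated stage-position data frame.
#' @export
rotate_positions <- function(positions, calib, angle_deg) {
  positions <- validate_positions(positions)
  stopifnot(inherits(calib, "rotation_calibration"), is.finite(angle_deg))
  th <- angle_deg * pi / 180
  dx <- positions$x_um - calib$centre_x_um
  dy <- positions$y_um - calib$centre_y_um
  positions$x_um <- calib$centre_x_um + cos(th) * dx - sin(th) * dy
  positions$y_um <- calib$centre_y_um + sin(th) * dx + cos(th) * dy
  positions
}

#' Save / load a rotation calibration as CSV
#'
#' Header `centre_x_um,centre_y_um`, one data row.
#'
#' @param calib a [rotation_calibration].
#' @param path CSV file path.
#' @return `load_calibration` returns a [rotation_calibration].
#' @export
save_calibration <- function(calib, path) {
  writeLines(c("centre_x_um,centre_y_um",
               sprintf("%.17g,%.17g", calib$centre_x_um, calib$centre_y_um)),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  df <- read.csv(path)
  if (!all(c("centre_x_um", "centre_y_um") %in% names(df)) || nrow(df) != 1)
    stop("malformed calibration file: ", path)
  rotation_calibration(df$centre_x_um, df$centre_y_um)
}
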
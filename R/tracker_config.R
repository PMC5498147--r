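#' Stage-axis convention
#'
#' Relates image axes (column = dx, row = dy; row increases downward) to
#' stage axes in micrometres. The mapping is hardware-dependent: a per-axis
#' sign and an optional x/y swap.
#'
#' @param sx,sy sign (+1 or -1) applied to the x and y components after the
#'   optional swap.
#' @param swap_xy if `TRUE`, image column maps to stage y and image row to
#'   stage x.
#' @return an `axis_map` object.
#' @export
axis_map <- function(sx = 1, sy = 1, swap_xy = FALSE) {
  if (!sx %in% c(-1, 1) || !sy %in% c(-1, 1)) stop("sx and sy must be +1 or -1")
  structure(list(sx = sx, sy = sy, swap_xy = isTRUE(swap_xy)),
            class = "axis_map")
}

apply_axis_map <- function(v, map) {
  # v = c(x, y) in image-derived coordinates
  if (map$swap_xy) v <- rev(v)
  c(v[1] * map$sx, v[2] * map$sy)
}

#' Tracker configuration
#'
#' Parameters of the per-time-point tracking computation. The tracking
#' window (region of interest) is a centred square whose side is
#' `roi_fraction` of the smaller frame dimension; one third of the field of
#' view is the default, sized so that a root growing at up to 300 um/h with
#' intervals of at most 30 min cannot escape between acquisitions on a
#' 20x-like field of view.
#'
#' @param roi_fraction fraction of the smaller frame dimension used as the
#'   tracking window side, in (0, 1]. Default 1/3.
#' @param mean_kernel_px odd kernel side of the moving-average filter variant.
#' @param median_kernel_px odd kernel side of the moving-median filter variant.
#' @param max_step_um safety limit: maximum per-step stage move (Euclidean
#'   norm, micrometres). A specimen whose predicted move exceeds it is
#'   stopped while the others continue.
#' @param tracking_channel 1-based channel used for tracking.
#' @param subpixel if `TRUE`, refine the correlation peak by parabolic
#'   interpolation; off by default (prediction does not require it).
#' @param axis_map an [axis_map] relating image to stage axes.
#' @return a `tracker_config` object.
#' @export
tracker_config <- function(roi_fraction = 1 / 3, mean_kernel_px = 3L,
                           median_kernel_px = 3L, max_step_um = 200,
                           tracking_channel = 1L, subpixel = FALSE,
                           axis_map = tiptrace::axis_map()) {
  if (!is.finite(roi_fraction) || roi_fraction <= 0 || roi_fraction > 1)
    stop("roi_fraction must be in (0, 1]")
  for (k in c(mean_kernel_px, median_kernel_px)) {
    if (k < 1 || k %% 2 == 0) stop("filter kernels must be odd and >= 1")
  }
  if (!is.finite(max_step_um) || max_step_um <= 0)
    stop("max_step_um must be > 0")
  structure(
    list(roi_fraction = roi_fraction,
         mean_kernel_px = as.integer(mean_kernel_px),
         median_kernel_px = as.integer(median_kernel_px),
         max_step_um = as.numeric(max_step_um),
         tracking_channel = as.integer(tracking_channel),
         subpixel = isTRUE(subpixel),
         axis_map = axis_map),
    class = "tracker_config")
}

#' Read / write a tracker configuration as flat key-value text
#'
#' The file holds one `key = value` pair per line; `#` starts a comment.
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path file path.
#' @param config a [tracker_config] (for writing).
#' @return `read_tracker_config` returns a [tracker_config].
#' @export
read_tracker_config <- function(path) {
  kv <- read_keyvalue(path)
  known <- c("roi_fraction", "mean_kernel_px", "median_kernel_px",
             "max_step_um", "tracking_channel", "subpixel",
             "axis_sx", "axis_sy", "axis_swap_xy")
  bad <- setdiff(names(kv), known)
  if (length(bad)) stop("unknown tracker config key(s): ",
                        paste(bad, collapse = ", "))
  defaults <- tracker_config()
  num <- function(key, fb) if (key %in% names(kv)) as.numeric(kv[[key]]) else fb
  lgl <- function(key, fb) if (key %in% names(kv))
    tolower(kv[[key]]) %in% c("true", "1", "yes") else fb
  tracker_config(
    roi_fraction = num("roi_fraction", defaults$roi_fraction),
    mean_kernel_px = num("mean_kernel_px", defaults$mean_kernel_px),
    median_kernel_px = num("median_kernel_px", defaults$median_kernel_px),
    max_step_um = num("max_step_um", defaults$max_step_um),
    tracking_channel = num("tracking_channel", defaults$tracking_channel),
    subpixel = lgl("subpixel", defaults$subpixel),
    axis_map = axis_map(sx = num("axis_sx", 1), sy = num("axis_sy", 1),
                        swap_xy = lgl("axis_swap_xy", FALSE)))
}

#' @rdname read_tracker_config
#' @export
write_tracker_config <- function(config, path) {
  stopifnot(inherits(config, "tracker_config"))
  lines <- c(
    sprintf("roi_fraction = %.17g", config$roi_fraction),
    sprintf("mean_kernel_px = %d", config$mean_kernel_px),
    sprintf("median_kernel_px = %d", config$median_kernel_px),
    sprintf("max_step_um = %.17g", config$max_step_um),
    sprintf("tracking_channel = %d", config$tracking_channel),
    sprintf("subpixel = %s", tolower(as.character(config$subpixel))),
    sprintf("axis_sx = %d", as.integer(config$axis_map$sx)),
    sprintf("axis_sy = %d", as.integer(config$axis_map$sy)),
    sprintf("axis_swap_xy = %s", tolower(as.character(config$axis_map$swap_xy))))
  writeLines(lines, path)
  invisible(path)
}

# Parse "key = value" lines into a named character list.
read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3)
      stop(sprintf("malformed config line %d: '%s'", i, lines[i]))
    kv[[m[2]]] <- trimws(m[3])
  }
  kv
}
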
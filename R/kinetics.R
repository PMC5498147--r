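#' Growth rates from a track log
#'
#' Derives per-interval growth rates (micrometres per hour) from the history
#' of recorded positions of each specimen.
#'
#' For a closed-loop track log (displacement columns present) the recorded
#' per-record displacement is itself the measured specimen motion during the
#' interval ending at that record, so the rate for interval
#' `(t[i-1], t[i]]` is `|delta(t[i])| / (t[i] - t[i-1])`. This attributes
#' each rate to the interval it actually measures and removes the one-step
#' latency of the predictive tracker from phase-resolved statistics. For a
#' plain position history (no displacement columns) the chord length between
#' consecutive positions is used. Both yield one fewer rate entry than
#' records; each entry is stamped with the interval midpoint. Records after
#' a specimen stopped are excluded.
#'
#' @param log track-log data frame ([run_session()]) or any data frame with
#'   `specimen_id`, `time_h`, `x_um`, `y_um` (and optionally `delta_x_um`,
#'   `delta_y_um`, `active`).
#' @param smooth_window optional odd integer: centred moving-average window
#'   applied to each specimen's rate series (no smoothing by default).
#' @return data frame `specimen_id`, `time_h` (interval midpoint),
#'   `rate_um_per_h`.
#' @export
growth_rates <- function(log, smooth_window = NULL) {
  need <- c("specimen_id", "time_h", "x_um", "y_um")
  if (!all(need %in% names(log)))
    stop("log must contain columns ", paste(need, collapse = ", "))
  closed_loop <- all(c("delta_x_um", "delta_y_um") %in% names(log)) &&
    any(!is.na(log$delta_x_um))
  out <- lapply(split(log, log$specimen_id), function(rec) {
    rec <- rec[order(rec$time_h), , drop = FALSE]
    if ("active" %in% names(rec)) {
      # keep the initial active stretch; a stopped specimen's frozen tail
      # carries no growth information
      keep <- cumprod(as.numeric(rec$active)) > 0
      rec <- rec[keep, , drop = FALSE]
    }
    n <- nrow(rec)
    if (n < 2) return(NULL)
    if (closed_loop) {
      i <- 2:n
      dist <- sqrt(rec$delta_x_um[i]^2 + rec$delta_y_um[i]^2)
    } else {
      i <- 2:n
      dist <- sqrt(diff(rec$x_um)^2 + diff(rec$y_um)^2)
    }
    dt <- diff(rec$time_h)
    data.frame(specimen_id = rec$specimen_id[1],
               time_h = (rec$time_h[i] + rec$time_h[i - 1]) / 2,
               rate_um_per_h = dist / dt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(data.frame(specimen_id = character(0),
                                      time_h = numeric(0),
                                      rate_um_per_h = numeric(0)))
  rownames(out) <- NULL
  if (!is.null(smooth_window)) {
    if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
    out <- do.call(rbind, lapply(split(out, out$specimen_id), function(s) {
      s$rate_um_per_h <- stats::filter(s$rate_um_per_h,
                                       rep(1 / smooth_window, smooth_window),
                                       sides = 2)
      s$rate_um_per_h <- as.numeric(s$rate_um_per_h)
      s
    }))
    rownames(out) <- NULL
  }
  out
}

#' Light schedules
#'
#' A light schedule is a data frame of non-overlapping half-open intervals
#' `[start_h, end_h)` with a logical `on` column, covering the session span.
#' `light_cycle()` builds a repeating day/night schedule starting with the
#' lights on.
#'
#' @param start_h,end_h,on interval bounds (hours) and illumination state.
#' @param span_h total span to cover.
#' @param on_h,off_h durations of the on and off phases of each cycle.
#' @return a light-schedule data frame.
#' @export
light_schedule <- function(start_h, end_h, on) {
  s <- data.frame(start_h = as.numeric(start_h), end_h = as.numeric(end_h),
                  on = as.logical(on))
  s <- s[order(s$start_h), , drop = FALSE]
  if (any(s$end_h <= s$start_h)) stop("schedule intervals must have end > start")
  if (nrow(s) > 1 && any(s$start_h[-1] < s$end_h[-nrow(s)]))
    stop("schedule intervals overlap")
  rownames(s) <- NULL
  s
}

#' @rdname light_schedule
#' @export
light_cycle <- function(span_h, on_h = 16, off_h = 8) {
  starts <- c()
  ends <- c()
  ons <- c()
  t <- 0
  on <- TRUE
  while (t < span_h) {
    d <- if (on) on_h else off_h
    starts <- c(starts, t)
    ends <- c(ends, min(t + d, span_h))
    ons <- c(ons, on)
    t <- t + d
    on <- !on
  }
  light_schedule(starts, ends, ons)
}

#' Annotate a growth series with the illumination state
#'
#' Labels each rate entry with the schedule state at its interval midpoint
#' (intervals are half-open `[start_h, end_h)`).
#'
#' @param series growth-rate data frame from [growth_rates()].
#' @param schedule a [light_schedule()] covering all entry times.
#' @return `series` with a logical `light_on` column added.
#' @export
annotate_light <- function(series, schedule) {
  idx <- vapply(series$time_h, function(t) {
    i <- which(schedule$start_h <= t & t < schedule$end_h)
    if (length(i) != 1)
      stop(sprintf("time %.4f h not covered by the light schedule", t))
    i
  }, integer(1))
  series$light_on <- schedule$on[idx]
  series
}

#' Root-tip angle relative to the gravity axis
#'
#' Angle of the organizing-centre-to-tip vector measured from the gravity
#' axis (image +y, pointing down), clockwise positive, in (-180, 180]
#' degrees. 0 degrees means the root grows straight down; +90 means the tip
#' points to the right of the organizing centre.
#'
#' @param tip,organizing_centre numeric length-2 vectors `c(x_um, y_um)`.
#' @return angle in degrees.
#' @export
tip_angle <- function(tip, organizing_centre) {
  v <- as.numeric(tip) - as.numeric(organizing_centre)
  if (all(v == 0)) stop("tip and organizing centre coincide")
  atan2(v[1], v[2]) * 180 / pi
}

#' Sum projection and upper/lower side intensity ratio
#'
#' Sum-projects a stack over z, then measures the mean intensity in two
#' congruent rectangles mirrored across a horizontal (or vertical) axis line
#' through the specimen, returning `upper / lower`. With a horizontal axis,
#' "upper" is the smaller-row side; with a vertical axis, the smaller-column
#' side.
#'
#' @param stack a [frame_stack] (or a plain matrix, used as-is).
#' @param axis_px 1-based row (horizontal axis) or column (vertical axis) of
#'   the mirror line.
#' @param centre_px 1-based column (horizontal axis) or row (vertical) on
#'   which the rectangles are centred along the axis.
#' @param box_px `c(length_along_axis, depth_from_axis)` rectangle size in
#'   pixels.
#' @param channel channel to project.
#' @param orientation `"horizontal"` or `"vertical"` axis line.
#' @param gap_px pixels left empty on each side of the axis line.
#' @return list `upper_mean`, `lower_mean`, `ratio` (upper / lower).
#' @export
sum_project_and_side_ratio <- function(stack, axis_px, centre_px,
                                       box_px = c(100L, 40L), channel = 1L,
                                       orientation = c("horizontal", "vertical"),
                                       gap_px = 0L) {
  orientation <- match.arg(orientation)
  if (inherits(stack, "frame_stack")) {
    d <- dim(stack$intensities)
    proj <- matrix(0, d[3], d[4])
    for (z in seq_len(d[2]))
      proj <- proj + matrix(stack$intensities[channel, z, , ], d[3], d[4])
  } else if (is.matrix(stack)) {
    proj <- stack
  } else stop("stack must be a frame_stack or a matrix")
  if (orientation == "vertical") proj <- t(proj)

  len <- as.integer(box_px[1])
  dep <- as.integer(box_px[2])
  c0 <- centre_px - floor(len / 2)
  cols <- c0:(c0 + len - 1)
  up_rows <- (axis_px - gap_px - dep):(axis_px - gap_px - 1)
  lo_rows <- (axis_px + gap_px + 1):(axis_px + gap_px + dep)
  if (min(cols) < 1 || max(cols) > ncol(proj) ||
      min(up_rows) < 1 || max(lo_rows) > nrow(proj))
    stop("measurement rectangles fall outside the image")
  upper <- mean(proj[up_rows, cols])
  lower <- mean(proj[lo_rows, cols])
  list(upper_mean = upper, lower_mean = lower, ratio = upper / lower)
}

#' Count new cross-walls between first-generation walls
#'
#' For a synthetic cell-file world, counts for each pair of walls adjacent
#' at `t0` how many new walls were created in `(t0, t1]` strictly between
#' them. After k synchronized division rounds every count is `2^k - 1`
#' (one round: each cell gains a midpoint wall; two rounds: 1 -> 2 -> 4
#' cells, i.e. 3 new walls).
#'
#' @param world a root scene world ([make_root_world()]).
#' @param t0,t1 observation window bounds in hours, `t0 < t1`.
#' @return integer vector, one count per adjacent wall pair at `t0`.
#' @export
count_membrane_generations <- function(world, t0, t1) {
  stopifnot(inherits(world, "scene_world"), t0 < t1)
  if (is.null(world$walls)) stop("world has no cell-file walls")
  walls <- world$walls(t1)
  first <- sort(walls$axial_um[walls$created_h <= t0])
  if (length(first) < 2) return(integer(0))
  new <- walls[walls$created_h > t0 & walls$created_h <= t1, , drop = FALSE]
  vapply(seq_len(length(first) - 1), function(i) {
    sum(new$axial_um > first[i] & new$axial_um < first[i + 1])
  }, integer(1))
}
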
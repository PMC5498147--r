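#' Stage position lists
#'
#' A position list is a data frame with one row per specimen and columns
#' `specimen_id`, `x_um`, `y_um`, `z_um`, `active`. Coordinates are
#' motorized-stage micrometres (continuous), distinct from image pixel
#' coordinates.
#'
#' @param specimen_id character vector of unique identifiers.
#' @param x_um,y_um stage coordinates in micrometres.
#' @param z_um optional z coordinate (pass-through; not used for tracking).
#' @param active logical; whether the specimen is still being tracked.
#' @return a validated stage-position data frame.
#' @export
stage_positions <- function(specimen_id, x_um, y_um, z_um = 0, active = TRUE) {
  validate_positions(data.frame(
    specimen_id = as.character(specimen_id),
    x_um = as.numeric(x_um), y_um = as.numeric(y_um),
    z_um = as.numeric(z_um), active = as.logical(active),
    stringsAsFactors = FALSE))
}

validate_positions <- function(positions) {
  need <- c("specimen_id", "x_um", "y_um", "z_um", "active")
  miss <- setdiff(need, names(positions))
  if (length(miss)) stop("position list missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(positions$specimen_id))
    stop("duplicate specimen_id in position list: ",
         paste(unique(positions$specimen_id[duplicated(positions$specimen_id)]),
               collapse = ", "))
  if (!all(is.finite(positions$x_um)) || !all(is.finite(positions$y_um)))
    stop("stage coordinates must be finite")
  positions[need]
}

#' Per-step stage-movement safety limit
#'
#' A tracker that loses its specimen can request excessive stage moves; to
#' protect the objective, any predicted per-step move whose Euclidean norm
#' exceeds `max_step_um` stops tracking of that specimen (the comparison is
#' inclusive: a move exactly at the limit is allowed).
#'
#' @param displacement the per-step stage move as a [displacement].
#' @param config a [tracker_config] providing `max_step_um`.
#' @return `TRUE` if the move is within the limit.
#' @export
check_safety_limit <- function(displacement, config = tracker_config()) {
  stopifnot(inherits(displacement, "displacement"))
  sqrt(displacement$dx_um^2 + displacement$dy_um^2) <= config$max_step_um
}

#' Number of imaging cycles in a session span
#'
#' Counts acquisitions at a fixed interval over a span, including both the
#' acquisition at time zero and the one at the end of the span (when the
#' span is an exact multiple of the interval).
#'
#' @param span_h total session span in hours.
#' @param interval_h acquisition interval in hours.
#' @return integer cycle count.
#' @export
imaging_cycles <- function(span_h, interval_h) {
  stopifnot(span_h >= 0, interval_h > 0)
  as.integer(floor(round(span_h / interval_h, 9)) + 1L)
}

#' Save / load a stage position list as CSV
#'
#' Columns `specimen_id,x_um,y_um,z_um,active` in that order; UTF-8, comma
#' separated, `.` decimal point, full double precision (round trips are
#' lossless).
#'
#' @param positions stage-position data frame.
#' @param path CSV file path.
#' @return `load_positions` returns the validated position data frame.
#' @export
save_positions <- function(positions, path) {
  positions <- validate_positions(positions)
  lines <- c("specimen_id,x_um,y_um,z_um,active",
             sprintf("%s,%.17g,%.17g,%.17g,%s",
                     positions$specimen_id, positions$x_um, positions$y_um,
                     positions$z_um, tolower(as.character(positions$active))))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_positions
#' @export
load_positions <- function(path) {
  if (!file.exists(path)) stop("position file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1 || trimws(lines[1]) != "specimen_id,x_um,y_um,z_um,active")
    stop("malformed position file (line 1): expected header ",
         "'specimen_id,x_um,y_um,z_um,active'")
  if (length(lines) == 1)
    return(stage_positions(character(0), numeric(0), numeric(0),
                           numeric(0), logical(0)))
  parse_row <- function(i) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(f) != 5)
      stop(sprintf("malformed position file (line %d): expected 5 columns, got %d",
                   i, length(f)))
    for (col in 2:4) {
      if (is.na(suppressWarnings(as.numeric(f[col]))))
        stop(sprintf("malformed position file (line %d, column %d): '%s' is not numeric",
                     i, col, f[col]))
    }
    f
  }
  rows <- t(vapply(2:length(lines), parse_row, character(5)))
  stage_positions(specimen_id = rows[, 1],
                  x_um = as.numeric(rows[, 2]),
                  y_um = as.numeric(rows[, 3]),
                  z_um = as.numeric(rows[, 4]),
                  active = tolower(rows[, 5]) %in% c("true", "1", "yes"))
}

#' Save / load a track log as CSV
#'
#' Columns `time_index,time_h,specimen_id,x_um,y_um,dx_px,dy_px,delta_x_um,
#' delta_y_um,active,stop_reason`. Shift and displacement entries are empty
#' at time index 0 (no predecessor frame). Round trips are lossless.
#'
#' @param log a track-log data frame as produced by [run_session()].
#' @param path CSV file path.
#' @return `load_track_log` returns the track-log data frame.
#' @export
save_track_log <- function(log, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  lines <- c(
    "time_index,time_h,specimen_id,x_um,y_um,dx_px,dy_px,delta_x_um,delta_y_um,active,stop_reason",
    sprintf("%d,%.17g,%s,%.17g,%.17g,%s,%s,%s,%s,%s,%s",
            log$time_index, log$time_h, log$specimen_id, log$x_um, log$y_um,
            fmt(log$dx_px), fmt(log$dy_px),
            fmt(log$delta_x_um), fmt(log$delta_y_um),
            tolower(as.character(log$active)), log$stop_reason))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_track_log
#' @export
load_track_log <- function(path) {
  if (!file.exists(path)) stop("track log not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(specimen_id = "character",
                                stop_reason = "character"))
  df$time_index <- as.integer(df$time_index)
  for (col in c("dx_px", "dy_px", "delta_x_um", "delta_y_um"))
    df[[col]] <- as.numeric(df[[col]])
  df$active <- as.logical(df$active)
  df
}

empty_track_log <- function() {
  data.frame(time_index = integer(0), time_h = numeric(0),
             specimen_id = character(0), x_um = numeric(0), y_um = numeric(0),
             dx_px = numeric(0), dy_px = numeric(0),
             delta_x_um = numeric(0), delta_y_um = numeric(0),
             active = logical(0), stop_reason = character(0),
             stringsAsFactors = FALSE)
}

#' Run a closed-loop tracking session
#'
#' Drives a microscope interface over `n_timepoints` acquisitions: at each
#' time point, acquire a z-stack per active specimen, project it, crop the
#' centred tracking window, estimate the shift against the previous time
#' point with the median-of-three correlation, update the cumulative
#' displacement, apply the safety limit, and load the predicted position
#' list for the next acquisition. Specimens stopped by the safety limit (or
#' by an untrackable blank frame) retain their last position and are
#' excluded from further shift computation; the others continue.
#'
#' @param microscope a microscope interface (see [simulated_microscope()]):
#'   a list with `load_positions(positions)`, `acquire(time_index, time_h)`
#'   returning a named list of [frame_stack]s for the active positions,
#'   `pixel_size` and `frame_dim`.
#' @param initial initial stage-position data frame (all rows active).
#' @param config a [tracker_config].
#' @param n_timepoints number of acquisitions (>= 1).
#' @param interval_h fixed acquisition interval in hours.
#' @param out_dir optional directory: when given, the position list and the
#'   track log are re-written after every time point (crash-safe, mirroring
#'   the store-then-read acquisition cycle).
#' @return the track log: one row per specimen per time point with stage
#'   position, measured shift (px), displacement (um), activity and stop
#'   reason (`none`, `safety_limit`, `zero_variance`, `user`).
#' @export
run_session <- function(microscope, initial, config = tracker_config(),
                        n_timepoints = 1L, interval_h = 1 / 3,
                        out_dir = NULL) {
  stopifnot(n_timepoints >= 1)
  positions <- validate_positions(initial)
  if (!all(positions$active)) stop("all initial positions must be active")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ids <- positions$specimen_id
  deltas <- stats::setNames(
    lapply(ids, function(i) displacement(0, 0)), ids)
  stop_reason <- stats::setNames(rep("none", length(ids)), ids)
  prev_roi <- stats::setNames(vector("list", length(ids)), ids)
  log <- empty_track_log()

  persist <- function() {
    if (is.null(out_dir)) return(invisible())
    save_positions(positions, file.path(out_dir, "positions.csv"))
    save_track_log(log, file.path(out_dir, "track_log.csv"))
  }

  for (t in seq_len(n_timepoints) - 1L) {
    time_h <- t * interval_h
    microscope$load_positions(positions)
    stacks <- tryCatch(microscope$acquire(t, time_h), error = function(e) {
      persist()
      stop("microscope acquisition failed at time index ", t, ": ",
           conditionMessage(e), call. = FALSE)
    })
    step_shift <- stats::setNames(
      rep(list(NULL), length(ids)), ids)

    for (id in ids) {
      i <- match(id, positions$specimen_id)
      if (!positions$active[i]) next
      stack <- stacks[[id]]
      if (is.null(stack)) stop("microscope returned no stack for active specimen '",
                               id, "'")
      mip <- max_intensity_project(stack, config$tracking_channel)
      roi <- crop_roi(mip, config$roi_fraction)
      if (t > 0L) {
        # the previous tracking window is searched within the full current
        # frame, so a displacement up to the window size keeps the template
        # fully overlapped
        search <- crop_search_window(mip, nrow(prev_roi[[id]]))
        if (sd(search) == 0 || sd(prev_roi[[id]]) == 0) {
          positions$active[i] <- FALSE
          stop_reason[id] <- "zero_variance"
        } else {
          sh <- robust_shift(prev_roi[[id]], search, config)
          cand <- update_displacement(deltas[[id]], sh, stack$pixel_size,
                                      config$axis_map)
          if (!check_safety_limit(cand, config)) {
            positions$active[i] <- FALSE
            stop_reason[id] <- "safety_limit"
          } else {
            deltas[[id]] <- cand
          }
          step_shift[[id]] <- sh
        }
      }
      prev_roi[[id]] <- roi
    }

    sh_or_na <- function(id, f) {
      s <- step_shift[[id]]
      if (is.null(s)) NA_real_ else s[[f]]
    }
    d_or_na <- function(id, f) {
      if (t == 0L) NA_real_ else deltas[[id]][[f]]
    }
    log <- rbind(log, data.frame(
      time_index = t, time_h = time_h, specimen_id = ids,
      x_um = positions$x_um[match(ids, positions$specimen_id)],
      y_um = positions$y_um[match(ids, positions$specimen_id)],
      dx_px = vapply(ids, sh_or_na, numeric(1), "dx_px"),
      dy_px = vapply(ids, sh_or_na, numeric(1), "dy_px"),
      delta_x_um = vapply(ids, d_or_na, numeric(1), "dx_um"),
      delta_y_um = vapply(ids, d_or_na, numeric(1), "dy_um"),
      active = positions$active[match(ids, positions$specimen_id)],
      stop_reason = unname(stop_reason[ids]),
      stringsAsFactors = FALSE))

    positions <- predict_positions(
      positions, deltas[positions$specimen_id[positions$active]])
    persist()
  }
  rownames(log) <- NULL
  log
}
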
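#' Specification of a synthetic growing-root scene
#'
#' Describes a root-tip-like specimen in continuous world coordinates: a
#' bright-walled tube (membrane-marker-like appearance: cell walls as bright
#' ridges on a dark background) whose tip advances along the integral of a
#' piecewise-constant speed profile, with a one-dimensional cell file behind
#' the tip in which every cell divides at fixed synchronized intervals by
#' inserting a new cross-wall at its midpoint.
#'
#' Defaults emulate an Arabidopsis primary root under long-term imaging:
#' growth of order 50-300 um/h (day/night modulation supported through the
#' speed profile), ~20 um meristematic cells, ~50 um tube radius.
#'
#' @param start_xy_um tip position at time 0, `c(x, y)` micrometres.
#' @param direction_deg growth direction measured from the +y gravity axis
#'   (downward), clockwise positive; 0 grows straight down.
#' @param speed_profile data frame `start_h`, `end_h`, `speed_um_per_h`
#'   (piecewise-constant speed, intervals half-open `[start, end)`).
#' @param curvature_deg_per_h constant turning rate of the growth direction
#'   (gravitropic bending); 0 grows straight.
#' @param cell_length_um initial cell length in the file (> 0).
#' @param n_cells number of cells in the initial file.
#' @param division_period_h every cell divides at each multiple of this
#'   period (synchronized rounds); `Inf` disables divisions.
#' @param root_radius_um tube radius.
#' @param cell_width_um target width of the longitudinal cell files across
#'   the tube (the rendered root holds several parallel files with
#'   staggered cross-walls, as a real meristem does).
#' @param wall_intensity,interior_intensity,background_intensity intensity
#'   levels (arbitrary digital numbers within 16-bit range).
#' @param wall_sigma_um Gaussian half-thickness of the rendered walls.
#' @param noise_sigma Gaussian read-noise standard deviation (DN).
#' @param sp_fraction salt-and-pepper fraction in [0, 0.5).
#' @param psf_sigma_px in-focus blur sigma in pixels; plane z is blurred
#'   with `psf_sigma_px * z` (defocus grows linearly with plane index).
#' @param seed integer seed; all randomness of the rendered scene flows
#'   from it.
#' @return a validated `synthetic_root_spec`.
#' @export
synthetic_root_spec <- function(start_xy_um = c(0, 0), direction_deg = 0,
                                speed_profile = data.frame(
                                  start_h = 0, end_h = Inf,
                                  speed_um_per_h = 150),
                                curvature_deg_per_h = 0,
                                cell_length_um = 20, n_cells = 30,
                                division_period_h = Inf,
                                root_radius_um = 50,
                                cell_width_um = 18,
                                wall_intensity = 3000,
                                interior_intensity = 180,
                                background_intensity = 100,
                                wall_sigma_um = 2,
                                noise_sigma = 0, sp_fraction = 0,
                                psf_sigma_px = 1, seed = 1L) {
  spec <- list(start_xy_um = as.numeric(start_xy_um),
               direction_deg = as.numeric(direction_deg),
               speed_profile = speed_profile,
               curvature_deg_per_h = as.numeric(curvature_deg_per_h),
               cell_length_um = as.numeric(cell_length_um),
               n_cells = as.integer(n_cells),
               division_period_h = as.numeric(division_period_h),
               root_radius_um = as.numeric(root_radius_um),
               cell_width_um = as.numeric(cell_width_um),
               wall_intensity = as.numeric(wall_intensity),
               interior_intensity = as.numeric(interior_intensity),
               background_intensity = as.numeric(background_intensity),
               wall_sigma_um = as.numeric(wall_sigma_um),
               noise_sigma = as.numeric(noise_sigma),
               sp_fraction = as.numeric(sp_fraction),
               psf_sigma_px = as.numeric(psf_sigma_px),
               seed = as.integer(seed))
  bad <- character(0)
  if (length(spec$start_xy_um) != 2 || !all(is.finite(spec$start_xy_um)))
    bad <- c(bad, "start_xy_um")
  sp <- spec$speed_profile
  if (!is.data.frame(sp) ||
      !all(c("start_h", "end_h", "speed_um_per_h") %in% names(sp)) ||
      any(sp$speed_um_per_h < 0) || any(sp$end_h <= sp$start_h))
    bad <- c(bad, "speed_profile")
  if (spec$cell_length_um <= 0) bad <- c(bad, "cell_length_um")
  if (spec$n_cells < 1) bad <- c(bad, "n_cells")
  if (spec$division_period_h <= 0) bad <- c(bad, "division_period_h")
  if (spec$root_radius_um <= 0) bad <- c(bad, "root_radius_um")
  if (spec$cell_width_um <= 0) bad <- c(bad, "cell_width_um")
  if (spec$sp_fraction < 0 || spec$sp_fraction >= 0.5)
    bad <- c(bad, "sp_fraction")
  if (spec$noise_sigma < 0) bad <- c(bad, "noise_sigma")
  if (spec$psf_sigma_px < 0) bad <- c(bad, "psf_sigma_px")
  if (length(bad)) stop("invalid synthetic root spec field(s): ",
                        paste(bad, collapse = ", "))
  structure(spec, class = "synthetic_root_spec")
}

# direction (radians from +y, clockwise positive) at time t
root_direction_rad <- function(spec, t) {
  (spec$direction_deg + spec$curvature_deg_per_h * t) * pi / 180
}

# arc length grown by time t (um): integral of the piecewise-constant speed
root_arc_length <- function(spec, t) {
  sp <- spec$speed_profile
  s <- 0
  for (i in seq_len(nrow(sp))) {
    lo <- max(0, sp$start_h[i])
    hi <- min(t, sp$end_h[i])
    if (hi > lo) s <- s + sp$speed_um_per_h[i] * (hi - lo)
  }
  s
}

# exact tip position: closed-form integral of speed * unit(direction(t))
# (the visible tip region — cap plus meristematic cell file — translates
# rigidly with the tip; wall stations are measured from the tip)
root_tip_position <- function(spec, t) {
  sp <- spec$speed_profile
  b <- spec$curvature_deg_per_h * pi / 180   # rad/h
  a0 <- spec$direction_deg * pi / 180
  pos <- spec$start_xy_um
  for (i in seq_len(nrow(sp))) {
    lo <- max(0, sp$start_h[i])
    hi <- min(t, sp$end_h[i])
    if (hi <= lo) next
    v <- sp$speed_um_per_h[i]
    if (b == 0) {
      pos <- pos + v * (hi - lo) * c(sin(a0), cos(a0))
    } else {
      # integral of (sin(a0 + b t), cos(a0 + b t)) dt
      pos <- pos + v / b * c(cos(a0 + b * lo) - cos(a0 + b * hi),
                             sin(a0 + b * hi) - sin(a0 + b * lo))
    }
  }
  pos
}

# wall stations (axial um, tip-relative: 0 = tip, negative behind) with
# creation times, replayed through the synchronized division rounds completed
# by time t. Initial cell lengths vary around cell_length_um (seeded), as in
# a real meristem; the aperiodic spacing also gives the correlation a unique
# peak, where a perfectly periodic lattice would be ambiguous.
root_walls <- function(spec, t) {
  lengths <- with_private_seed(
    mix_seed(spec$seed, 13L),
    spec$cell_length_um * runif(spec$n_cells, 0.6, 1.4))
  stations <- -c(0, cumsum(lengths))
  created <- rep(0, length(stations))
  if (is.finite(spec$division_period_h)) {
    rounds <- floor(t / spec$division_period_h)
    for (j in seq_len(max(0, rounds))) {
      ord <- order(stations)
      stations <- stations[ord]
      created <- created[ord]
      mid <- (stations[-1] + stations[-length(stations)]) / 2
      stations <- c(stations, mid)
      created <- c(created, rep(j * spec$division_period_h, length(mid)))
    }
  }
  ord <- order(stations)
  data.frame(axial_um = stations[ord], created_h = created[ord])
}

#' Build a growing-root scene world
#'
#' A scene world is a continuous-coordinate model that can be rendered at
#' any stage window and time ([render_view()]) and queried for ground truth
#' (exact tip position, wall stations and creation times). The rendered
#' cell file lies along the current growth axis behind the tip; walls
#' appear as bright Gaussian ridges (cross-walls, lateral walls and a tip
#' cap) on a dim interior. Wall stations are tip-relative (0 = tip,
#' negative behind): the visible tip region translates rigidly with the
#' advancing tip, as the meristem of a growing root does.
#'
#' @param spec a [synthetic_root_spec()].
#' @return a `scene_world` with functions `intensity(X, Y, time_h)`,
#'   `tip(time_h)`, `walls(time_h)` and `direction(time_h)`.
#' @export
make_root_world <- function(spec = synthetic_root_spec()) {
  stopifnot(inherits(spec, "synthetic_root_spec"))
  tail_um <- spec$n_cells * spec$cell_length_um

  # deterministic texture hash in [0, 1)
  hash01 <- function(a, b) ((sin(a * 127.1 + b * 311.7 +
                                 spec$seed * 0.618) * 43758.5453) %% 1)
  n_files <- max(1L, round(2 * spec$root_radius_um / spec$cell_width_um))
  fw <- 2 * spec$root_radius_um / n_files

  intensity <- function(X, Y, time_h) {
    tip <- root_tip_position(spec, time_h)
    a <- root_direction_rad(spec, time_h)
    u <- c(sin(a), cos(a))
    s_t <- root_arc_length(spec, time_h)
    relx <- X - tip[1]
    rely <- Y - tip[2]
    axial <- relx * u[1] + rely * u[2]        # > 0 ahead of the tip
    perp_s <- relx * u[2] - rely * u[1]       # signed cross-axis offset
    perp <- abs(perp_s)
    w <- spec$wall_sigma_um
    r <- spec$root_radius_um
    # the apex tapers over ~2.5 radii: local radius follows a rounded
    # (elliptic) profile, so walls near the tip converge obliquely toward
    # the apex as in a real root tip
    taper <- 2.5 * r
    u_t <- pmin(1, pmax(0, -axial / taper))
    scale <- sqrt(pmax(0, u_t * (2 - u_t)))
    r_loc <- r * scale
    in_tube <- (axial <= 0) & (axial >= -(s_t + tail_um)) & (perp <= r_loc)

    walls <- root_walls(spec, time_h)
    stations <- sort(walls$axial_um[walls$created_h <= time_h])

    ridge <- matrix(0, nrow(X), ncol(X))
    interior <- matrix(1, nrow(X), ncol(X))

    # longitudinal walls between files (and the two flanks), following the
    # taper, with per-cell segment brightness: marker expression varies cell
    # to cell, so no wall renders as a uniform line (a uniform axis-parallel
    # line would carry no axial information)
    ci_long <- findInterval(axial, stations)
    in_ax <- (axial <= 0) & (axial >= -(s_t + tail_um))
    for (j in 0:n_files) {
      p_j <- -r + j * fw
      seg <- 0.7 + 0.3 * hash01(j * 13 + 5, ci_long)
      lng <- seg * exp(-(perp_s - p_j * scale)^2 / (2 * w^2)) * in_ax
      ridge <- pmax(ridge, lng)
    }

    # per-file cross-walls (staggered between files) and per-cell interior
    # brightness
    fi <- pmin(n_files - 1, pmax(0, floor((perp_s + r) / fw)))
    for (k in 0:(n_files - 1)) {
      jit <- if (k == n_files %/% 2) 0 else
        (hash01(k + 1, 17) - 0.5) * spec$cell_length_um
      st_k <- stations + jit
      mask <- in_tube & (fi == k)
      if (!any(mask)) next
      ax <- axial[mask]
      ci <- findInterval(ax, st_k)
      interior[mask] <- 0.7 + 0.6 * hash01(k * 7 + 1, ci)
      # distance and brightness of the nearest cross-wall
      lo_i <- pmax(ci, 1L)
      hi_i <- pmin(ci + 1L, length(st_k))
      d_lo <- abs(ax - st_k[lo_i])
      d_hi <- abs(ax - st_k[hi_i])
      near <- ifelse(d_lo <= d_hi, lo_i, hi_i)
      d <- pmin(d_lo, d_hi)
      bright <- 0.7 + 0.3 * hash01(k * 29 + 3, near)
      cr <- matrix(0, nrow(X), ncol(X))
      cr[mask] <- bright * exp(-d^2 / (2 * w^2))
      ridge <- pmax(ridge, cr)
    }

    # tip cap
    dist_tip <- sqrt(relx^2 + rely^2)
    cap <- exp(-(dist_tip - r)^2 / (2 * w^2)) * (axial > -r)
    ridge <- pmax(ridge, cap)

    spec$background_intensity +
      (spec$interior_intensity * interior - spec$background_intensity) * in_tube +
      (spec$wall_intensity - spec$background_intensity) * ridge
  }

  structure(list(
    kind = "root", seed = spec$seed, spec = spec,
    intensity = intensity,
    tip = function(time_h) root_tip_position(spec, time_h),
    walls = function(time_h) {
      w <- root_walls(spec, time_h)
      w[w$created_h <= time_h, , drop = FALSE]
    },
    direction = function(time_h) root_direction_rad(spec, time_h) * 180 / pi,
    noise = list(sigma = spec$noise_sigma, sp_fraction = spec$sp_fraction),
    psf_sigma_px = spec$psf_sigma_px,
    background = spec$background_intensity),
    class = "scene_world")
}

#' Build a migrating cell-cluster scene world
#'
#' A generic moving specimen (prechordal-plate-like): a blob of overlapping
#' soft-edged disk cells jittering about a moving centroid. Demonstrates
#' that the tracker makes no assumption about specimen shape or brightness.
#'
#' @param centroid_path function `time_h -> c(x_um, y_um)`.
#' @param n_cells number of cells in the blob.
#' @param cell_radius_um radius of one cell.
#' @param spread_um standard deviation of the fixed cell offsets around the
#'   centroid.
#' @param jitter_um amplitude of the slow per-cell positional jitter.
#' @param cell_intensity,background_intensity intensity levels (DN).
#' @param noise_sigma,sp_fraction,psf_sigma_px noise and blur as in
#'   [synthetic_root_spec()].
#' @param seed integer seed.
#' @return a `scene_world` with `intensity(X, Y, time_h)` and
#'   `centroid(time_h)` (ground truth = the path).
#' @export
make_cluster_world <- function(centroid_path, n_cells = 25,
                               cell_radius_um = 12, spread_um = 30,
                               jitter_um = 1.5,
                               cell_intensity = 2500,
                               background_intensity = 100,
                               noise_sigma = 0, sp_fraction = 0,
                               psf_sigma_px = 1, seed = 1L) {
  stopifnot(is.function(centroid_path), n_cells >= 1)
  cells <- with_private_seed(seed, data.frame(
    ox = rnorm(n_cells, sd = spread_um),
    oy = rnorm(n_cells, sd = spread_um),
    freq = runif(n_cells, 0.05, 0.2),       # cycles per hour
    phase = runif(n_cells, 0, 2 * pi)))
  if (n_cells == 1) { cells$ox <- 0; cells$oy <- 0 }

  intensity <- function(X, Y, time_h) {
    ctr <- centroid_path(time_h)
    acc <- matrix(0, nrow(X), ncol(X))
    edge <- cell_radius_um / 4
    for (i in seq_len(n_cells)) {
      jx <- jitter_um * sin(2 * pi * (cells$freq[i] * time_h) + cells$phase[i])
      jy <- jitter_um * cos(2 * pi * (cells$freq[i] * time_h) + cells$phase[i])
      d <- sqrt((X - ctr[1] - cells$ox[i] - jx)^2 +
                (Y - ctr[2] - cells$oy[i] - jy)^2)
      # soft-edged disk
      acc <- pmax(acc, pmin(1, pmax(0, (cell_radius_um - d) / edge + 1)))
    }
    background_intensity + (cell_intensity - background_intensity) * acc
  }

  structure(list(
    kind = "cluster", seed = as.integer(seed),
    intensity = intensity,
    centroid = function(time_h) centroid_path(time_h),
    tip = function(time_h) centroid_path(time_h),
    noise = list(sigma = noise_sigma, sp_fraction = sp_fraction),
    psf_sigma_px = psf_sigma_px,
    background = background_intensity),
    class = "scene_world")
}

#' Rotate a scene world about a centre
#'
#' Returns a world physically rotated by `angle_deg` (clockwise positive in
#' the displayed image, matching [rotate_positions()]) about `centre_um`,
#' optionally perturbed by a Gaussian mechanical centre error, emulating the
#' slight imperfection of a real rotation stage.
#'
#' @param world a `scene_world`.
#' @param centre_um `c(x, y)` rotation centre (micrometres).
#' @param angle_deg rotation angle, clockwise positive.
#' @param centre_error_sigma_um standard deviation of the mechanical centre
#'   error; the actual rotation axis is drawn once per call.
#' @param seed seed for the centre error draw.
#' @return the rotated `scene_world`.
#' @export
rotate_world <- function(world, centre_um, angle_deg,
                         centre_error_sigma_um = 0, seed = 1L) {
  stopifnot(inherits(world, "scene_world"))
  centre <- as.numeric(centre_um)
  if (centre_error_sigma_um > 0) {
    centre <- centre + with_private_seed(mix_seed(seed, angle_deg),
                                         rnorm(2, sd = centre_error_sigma_um))
  }
  th <- angle_deg * pi / 180
  fwd <- function(x, y) list(x = centre[1] + cos(th) * (x - centre[1]) - sin(th) * (y - centre[2]),
                             y = centre[2] + sin(th) * (x - centre[1]) + cos(th) * (y - centre[2]))
  inv <- function(x, y) list(x = centre[1] + cos(th) * (x - centre[1]) + sin(th) * (y - centre[2]),
                             y = centre[2] - sin(th) * (x - centre[1]) + cos(th) * (y - centre[2]))
  out <- world
  out$intensity <- function(X, Y, time_h) {
    p <- inv(X, Y)
    world$intensity(p$x, p$y, time_h)
  }
  out$tip <- function(time_h) {
    t0 <- world$tip(time_h)
    p <- fwd(t0[1], t0[2])
    c(p$x, p$y)
  }
  if (!is.null(world$centroid)) out$centroid <- out$tip
  out$seed <- mix_seed(world$seed, angle_deg, 7L)
  out
}

#' Render a stage window of a scene world as a frame stack
#'
#' Evaluates the world intensity on the pixel grid of a frame centred at
#' the stage position, blurs plane z with sigma `psf_sigma_px * z` (defocus
#' growing linearly with depth), applies Gaussian read noise and
#' salt-and-pepper pixels, and quantizes to 16-bit integers. Fully
#' deterministic given the world seed and the arguments.
#'
#' @param world a `scene_world`.
#' @param stage single-row stage-position data frame or list with `x_um`,
#'   `y_um`.
#' @param frame_px `c(rows, cols)` frame size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param n_z number of z planes (>= 1).
#' @param time_h acquisition time in hours.
#' @param time_index acquisition index recorded in the stack.
#' @param specimen_id identifier recorded in the stack.
#' @return a [frame_stack] with one channel.
#' @export
render_view <- function(world, stage, frame_px = c(512L, 512L),
                        pixel_size = 1, n_z = 1L, time_h = 0,
                        time_index = 0L, specimen_id = "s1") {
  stopifnot(inherits(world, "scene_world"), n_z >= 1)
  h <- as.integer(frame_px[1])
  w <- as.integer(frame_px[2])
  cx <- as.numeric(stage$x_um[1])
  cy <- as.numeric(stage$y_um[1])
  xs <- cx + (seq_len(w) - 1 - (w - 1) / 2) * pixel_size
  ys <- cy + (seq_len(h) - 1 - (h - 1) / 2) * pixel_size
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)
  ideal <- world$intensity(X, Y, time_h)

  arr <- array(0, dim = c(1L, n_z, h, w))
  for (z in seq_len(n_z)) {
    plane <- .gaussian_blur_cpp(ideal, world$psf_sigma_px * z)
    sig <- world$noise$sigma
    spf <- world$noise$sp_fraction
    if (sig > 0 || spf > 0) {
      sd_seed <- mix_seed(world$seed, time_h * 3600, z, cx * 16, cy * 16)
      plane <- with_private_seed(sd_seed, {
        if (sig > 0) plane <- plane + rnorm(length(plane), sd = sig)
        if (spf > 0) {
          n_sp <- round(spf * length(plane))
          idx <- sample.int(length(plane), n_sp)
          vals <- ifelse(runif(n_sp) < 0.5, 0, 65535)
          plane[idx] <- vals
        }
        plane
      })
    }
    arr[1L, z, , ] <- pmin(65535, pmax(0, round(plane)))
  }
  frame_stack(arr, pixel_size = pixel_size, time_index = time_index,
              time_h = time_h, specimen_id = specimen_id)
}

#' Simulated microscope over scene worlds
#'
#' Implements the microscope interface consumed by [run_session()]: accepts
#' a position list, acquires one rendered z-stack per active position
#' (perturbing the requested stage coordinates by a Gaussian repositioning
#' error), and reports pixel size and frame dimensions.
#'
#' @param worlds named list of `scene_world`s, one per specimen id.
#' @param frame_px `c(rows, cols)` frame size.
#' @param pixel_size micrometres per pixel.
#' @param n_z z planes per acquisition.
#' @param stage_error_sigma_um standard deviation of the stage
#'   repositioning error (micrometres; 0 = perfect stage).
#' @param seed seed of the stage-error stream.
#' @return a microscope interface: list with `load_positions`, `acquire`,
#'   `pixel_size`, `frame_dim`, and `last_positions()` for inspection.
#' @export
simulated_microscope <- function(worlds, frame_px = c(512L, 512L),
                                 pixel_size = 1, n_z = 1L,
                                 stage_error_sigma_um = 0, seed = 1L) {
  stopifnot(is.list(worlds), length(names(worlds)) == length(worlds))
  state <- new.env(parent = emptyenv())
  state$positions <- NULL

  load_positions <- function(positions) {
    positions <- validate_positions(positions)
    unknown <- setdiff(positions$specimen_id, names(worlds))
    if (length(unknown))
      stop("unknown specimen_id: ", paste(unknown, collapse = ", "))
    state$positions <- positions
    invisible(TRUE)
  }
  acquire <- function(time_index, time_h) {
    if (is.null(state$positions)) stop("no position list loaded")
    pos <- state$positions
    out <- list()
    for (i in seq_len(nrow(pos))) {
      if (!pos$active[i]) next
      id <- pos$specimen_id[i]
      err <- c(0, 0)
      if (stage_error_sigma_um > 0) {
        err <- with_private_seed(mix_seed(seed, time_index, i),
                                 rnorm(2, sd = stage_error_sigma_um))
      }
      actual <- list(x_um = pos$x_um[i] + err[1], y_um = pos$y_um[i] + err[2])
      out[[id]] <- render_view(worlds[[id]], actual, frame_px = frame_px,
                               pixel_size = pixel_size, n_z = n_z,
                               time_h = time_h, time_index = time_index,
                               specimen_id = id)
    }
    out
  }
  list(load_positions = load_positions, acquire = acquire,
       pixel_size = pixel_size, frame_dim = as.integer(frame_px),
       last_positions = function() state$positions)
}
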
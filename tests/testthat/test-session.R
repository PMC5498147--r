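test_that("safety limit compares the per-step move norm inclusively", {
  cfg <- tracker_config(max_step_um = 200)
  expect_true(check_safety_limit(displacement(0, 0), cfg))
  expect_true(check_safety_limit(displacement(120, 160), cfg))   # norm 200
  expect_false(check_safety_limit(displacement(150, 160), cfg))  # norm 219.3
})

test_that("imaging cycle counting includes both endpoints", {
  expect_equal(imaging_cycles(1, 1 / 3), 4L)
  expect_equal(imaging_cycles(0, 1), 1L)
})

test_that("position lists round trip losslessly through CSV", {
  pos <- stage_positions(c("r1", "r2", "r3"),
                         x_um = c(0.1234567890123, -5000, 1e6 / 3),
                         y_um = c(pi, 0, -2 / 7),
                         z_um = c(0, 1.5, -0.25),
                         active = c(TRUE, FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".csv")
  save_positions(pos, f)
  expect_equal(load_positions(f), pos)

  # empty list: header-only file
  empty <- pos[0, ]
  save_positions(empty, f)
  back <- load_positions(f)
  expect_equal(nrow(back), 0L)
  expect_equal(names(back), names(pos))
})

test_that("malformed or duplicated position files are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,x_um,y_um,z_um,active",
               "a,1,2,0,true", "a,3,4,0,true"), f)
  expect_error(load_positions(f), "duplicate specimen_id")

  writeLines(c("specimen_id,x_um,y_um,z_um,active", "a,1,oops,0,true"), f)
  expect_error(load_positions(f), "line 2, column 3")

  writeLines(c("wrong,header"), f)
  expect_error(load_positions(f), "line 1")

  writeLines(c("specimen_id,x_um,y_um,z_um,active", "a,1,2,0"), f)
  expect_error(load_positions(f), "line 2")
})

test_that("a single-time-point session records no shifts", {
  w <- test_root_world()
  mic <- simulated_microscope(list(r1 = w), frame_px = c(96, 96),
                              pixel_size = 1)
  log <- run_session(mic, stage_positions("r1", 0, 0), tracker_config(),
                     n_timepoints = 1)
  expect_equal(nrow(log), 1L)
  expect_true(all(is.na(log$dx_px)))
  expect_true(all(is.na(log$delta_x_um)))
  expect_true(all(log$active))
  expect_equal(log$stop_reason, "none")
})

test_that("closed loop converges on a constant-velocity root", {
  # 150 um/h at 20-min intervals = 50 um/step
  w <- test_root_world(speed = 150, seed = 4)
  mic <- simulated_microscope(list(r1 = w), frame_px = c(320, 320),
                              pixel_size = 1, n_z = 2)
  log <- run_session(mic, stage_positions("r1", 0, 0),
                     tracker_config(max_step_um = 300),
                     n_timepoints = 8, interval_h = 1 / 3)
  dy <- diff(log$y_um)
  expect_true(all(abs(dy[-1] - 50) < 2))     # ~50 um advance per step
  # residual shift is zero from the third time point onward
  expect_true(all(abs(log$dy_px[-(1:2)]) == 0))
  expect_true(all(abs(log$dx_px[-1]) <= 1))
  final <- log[nrow(log), ]
  expect_lt(sqrt(final$dx_px^2 + final$dy_px^2), 2)
  # tip offset from frame centre stays bounded by one interval's motion
  tip_end <- w$tip(final$time_h)
  expect_lt(sqrt(sum((tip_end - c(final$x_um, final$y_um))^2)), 50 + 1e-9)
})

test_that("a 300 um/h root is never lost at 30-min intervals (window rule)", {
  # 640 um field of view, tracking window one third: worst-case guidance
  w <- test_root_world(speed = 300, seed = 8)
  mic <- simulated_microscope(list(r1 = w), frame_px = c(640, 640),
                              pixel_size = 1, n_z = 1)
  log <- run_session(mic, stage_positions("r1", 0, 0),
                     tracker_config(max_step_um = 400),
                     n_timepoints = 10, interval_h = 0.5)
  expect_true(all(log$active))
  for (i in seq_len(nrow(log))) {
    tip <- w$tip(log$time_h[i])
    off <- sqrt(sum((tip - c(log$x_um[i], log$y_um[i]))^2))
    expect_lt(off, 640 / 2)   # tip always inside the frame
  }
  # converged: last recorded steps match the programmed 150 um/step
  expect_equal(diff(log$y_um)[9], 150, tolerance = 0.02)
})

test_that("a teleported specimen is stopped by the safety limit, others continue", {
  # low-magnification geometry: 10 um/px, 3840 um field of view
  wj <- teleport_cluster_world(jump = 500, jump_h = 1, seed = 2)
  wk <- make_cluster_world(function(t) c(0, 30 * t), n_cells = 12,
                           cell_radius_um = 60, spread_um = 150,
                           jitter_um = 0, psf_sigma_px = 0.5, seed = 3)
  mic <- simulated_microscope(list(jumpy = wj, steady = wk),
                              frame_px = c(384, 384), pixel_size = 10)
  init <- stage_positions(c("jumpy", "steady"), c(0, 0), c(0, 0))
  log <- run_session(mic, init, tracker_config(max_step_um = 200),
                     n_timepoints = 6, interval_h = 1 / 3)
  j <- log[log$specimen_id == "jumpy", ]
  s <- log[log$specimen_id == "steady", ]
  expect_true(all(j$active[j$time_index < 3]))
  expect_false(any(j$active[j$time_index >= 3]))
  expect_equal(unique(j$stop_reason[j$time_index >= 3]), "safety_limit")
  # frozen position after the stop
  expect_equal(unique(j$x_um[j$time_index >= 3]), j$x_um[j$time_index == 3])
  expect_equal(unique(j$y_um[j$time_index >= 3]), j$y_um[j$time_index == 3])
  # the other specimen is tracked to the end
  expect_true(all(s$active))
  expect_equal(s$stop_reason, rep("none", 6))
})

test_that("a blank acquisition stops the specimen as untrackable", {
  blank <- structure(list(
    kind = "blank", seed = 1L,
    intensity = function(X, Y, t) matrix(100, nrow(X), ncol(X)),
    tip = function(t) c(0, 0),
    noise = list(sigma = 0, sp_fraction = 0),
    psf_sigma_px = 0, background = 100), class = "scene_world")
  mic <- simulated_microscope(list(b = blank), frame_px = c(64, 64),
                              pixel_size = 1)
  log <- run_session(mic, stage_positions("b", 0, 0), tracker_config(),
                     n_timepoints = 3)
  expect_false(any(log$active[log$time_index >= 1]))
  expect_equal(unique(log$stop_reason[log$time_index >= 1]), "zero_variance")
})

test_that("track logs round trip through CSV and persist during the session", {
  w <- test_root_world(speed = 90, seed = 6)
  out <- withr::local_tempdir()
  mic <- simulated_microscope(list(r1 = w), frame_px = c(128, 128),
                              pixel_size = 1)
  log <- run_session(mic, stage_positions("r1", 0, 0),
                     tracker_config(max_step_um = 300),
                     n_timepoints = 4, out_dir = out)
  expect_true(file.exists(file.path(out, "track_log.csv")))
  expect_true(file.exists(file.path(out, "positions.csv")))
  expect_equal(load_track_log(file.path(out, "track_log.csv")), log)
  # persisted position list equals the final prediction
  pos <- load_positions(file.path(out, "positions.csv"))
  last <- log[log$time_index == 3, ]
  expect_equal(pos$x_um, last$x_um + last$delta_x_um)
  expect_equal(pos$y_um, last$y_um + last$delta_y_um)
})

test_that("tracker configs round trip through key-value files", {
  cfg <- tracker_config(roi_fraction = 0.25, mean_kernel_px = 5,
                        median_kernel_px = 3, max_step_um = 123.5,
                        tracking_channel = 2, subpixel = TRUE,
                        axis_map = axis_map(sx = -1, swap_xy = TRUE))
  f <- withr::local_tempfile(fileext = ".cfg")
  write_tracker_config(cfg, f)
  expect_equal(read_tracker_config(f), cfg)

  writeLines("roi_fraction = 0.5\nbogus_key = 1", f)
  expect_error(read_tracker_config(f), "unknown tracker config key")
})
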
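test_that("max intensity projection collapses z per pixel", {
  # single plane: identity
  m <- matrix(1:12, 3, 4)
  st <- frame_stack(m, pixel_size = 1)
  expect_equal(max_intensity_project(st, 1), m, ignore_attr = FALSE)

  # max with an all-zero plane leaves the other plane
  arr <- array(0, dim = c(1, 2, 3, 4))
  arr[1, 2, , ] <- m
  expect_identical(max_intensity_project(frame_stack(arr, 1), 1), m * 1)

  # random 4-plane stack against an exhaustive per-pixel loop
  set.seed(11)
  arr <- array(runif(2 * 4 * 5 * 6), dim = c(2, 4, 5, 6))
  got <- max_intensity_project(frame_stack(arr, 1), 2)
  want <- matrix(0, 5, 6)
  for (r in 1:5) for (c in 1:6) want[r, c] <- max(arr[2, , r, c])
  expect_equal(got, want)

  # invariant to z-order permutation
  perm <- arr[, c(3, 1, 4, 2), , ]
  expect_equal(max_intensity_project(frame_stack(perm, 1), 2), want)

  expect_error(max_intensity_project(frame_stack(arr, 1), 5), "channel")
})

test_that("ROI crop is the centred square of the stated side", {
  img <- matrix(seq_len(1400 * 1400), 1400, 1400)
  cr <- crop_roi(img, 1 / 3)
  expect_equal(dim(cr), c(466L, 466L))  # floor(1400 / 3)
  expect_equal(cr, img[468:933, 468:933])

  expect_identical(crop_roi(img, 1), img)

  small <- matrix(1:81, 9, 9)
  expect_equal(crop_roi(small, 1 / 3), small[4:6, 4:6])

  expect_error(crop_roi(img, 0), "roi_fraction")
  expect_error(crop_roi(img, 1.5), "roi_fraction")
})

test_that("filter variants behave on constants, identity kernels and hot pixels", {
  cfg <- tracker_config()
  const <- matrix(7, 6, 6)
  v <- filter_variants(const, cfg)
  expect_equal(v$raw, const)
  expect_equal(v$mean, const)
  expect_equal(v$median, const)

  cfg1 <- tracker_config(mean_kernel_px = 1, median_kernel_px = 1)
  img <- rand_texture(8, 2)
  v1 <- filter_variants(img, cfg1)
  expect_equal(v1$mean, img)
  expect_equal(v1$median, img)

  # single hot pixel: removed by the median, spread to 1/9 by the mean
  hot <- matrix(0, 5, 5); hot[3, 3] <- 9
  vh <- filter_variants(hot, cfg)
  expect_equal(vh$median, matrix(0, 5, 5))
  expect_equal(vh$mean[2:4, 2:4], matrix(1, 3, 3))
  expect_equal(vh$mean[1, 1], 0)

  # replicate borders: a corner pixel appears 4 times in its 3x3 window
  corner <- matrix(0, 5, 5); corner[1, 1] <- 9
  vc <- filter_variants(corner, cfg)
  expect_equal(vc$mean[1, 1], 4)
  expect_equal(vc$median[1, 1], 0)

  expect_error(tracker_config(mean_kernel_px = 2), "odd")
})

test_that("cross-correlation surface equals the brute-force direct oracle", {
  set.seed(3)
  ref <- rand_texture(32, 31)
  cur <- roll(ref, -3, 5)
  got <- xcorr_surface(ref, cur)
  want <- bf_xcorr(ref, cur)
  expect_equal(got$dy_lags, want$dy_lags)
  expect_equal(got$dx_lags, want$dx_lags)
  expect_equal(got$surface, want$surface, tolerance = 1e-6)

  # and on a non-matching pair
  cur2 <- rand_texture(32, 77)
  expect_equal(xcorr_surface(ref, cur2)$surface, bf_xcorr(ref, cur2)$surface,
               tolerance = 1e-6)
})

test_that("integer shifts are recovered exactly from circular constructions", {
  expect_equal(unlist(xcorr_shift(rand_texture(48, 5), rand_texture(48, 5))[c("dx_px", "dy_px")],
                      use.names = FALSE), c(0, 0))
  for (seed in 1:20) {
    set.seed(seed + 100)
    ref <- rand_texture(64, seed)
    dx <- sample(-15:15, 1); dy <- sample(-15:15, 1)   # |shift| < ROI/4
    s <- xcorr_shift(ref, roll(ref, dy, dx))
    expect_equal(c(s$dx_px, s$dy_px), c(dx, dy))
  }
})

test_that("degenerate correlation inputs raise explicit errors", {
  expect_error(xcorr_shift(matrix(1, 8, 8), rand_texture(8, 1)),
               "zero-variance")
  expect_error(xcorr_shift(rand_texture(8, 1), matrix(0, 8, 8)),
               "zero-variance")
  expect_error(xcorr_surface(rand_texture(16, 1), rand_texture(8, 1)),
               "dimension mismatch")
  expect_error(xcorr_surface(rand_texture(8, 1), rand_texture(11, 1)),
               "even margin")
})

test_that("subpixel refinement resolves a fractional offset", {
  n <- 64
  pattern <- function(off) {
    x <- outer(rep(1, n), 1:n)
    y <- outer(1:n, rep(1, n))
    s <- matrix(0, n, n)
    set.seed(7)
    for (k in 1:12) {
      fx <- runif(1, 0.02, 0.12); fy <- runif(1, 0.02, 0.12)
      ph <- runif(1, 0, 2 * pi)
      s <- s + sin(2 * pi * (fx * (x - off) + fy * y) + ph)
    }
    s
  }
  sh <- xcorr_shift(pattern(0), pattern(2.5), subpixel = TRUE)
  expect_lt(abs(sh$dx_px - 2.5), 0.3)
})

test_that("median-of-three fusion discards one outlying variant", {
  expect_equal(median(c(2, 2, 40)), 2)   # component-wise median rule

  # all variants agree on a clean pair
  ref <- rand_texture(64, 9)
  cur <- roll(ref, 4, -2)
  s <- robust_shift(ref, cur, tracker_config())
  expect_equal(c(s$dx_px, s$dy_px), c(-2, 4))

  # root-like frame pair, true shift (8, 20), 5% salt-and-pepper on cur
  w <- test_root_world(seed = 21)
  st0 <- render_view(w, list(x_um = 0, y_um = 0), frame_px = c(160, 160),
                     pixel_size = 1, time_h = 0)
  ref <- max_intensity_project(st0, 1)
  st1 <- render_view(w, list(x_um = -8, y_um = -20), frame_px = c(160, 160),
                     pixel_size = 1, time_h = 0)
  cur <- max_intensity_project(st1, 1)
  set.seed(5)
  idx <- sample(length(cur), round(0.05 * length(cur)))
  cur[idx] <- ifelse(runif(length(idx)) < 0.5, min(cur), max(cur))
  s <- robust_shift(ref, cur, tracker_config())
  expect_equal(c(s$dx_px, s$dy_px), c(8, 20))
})

test_that("fused shift is bounded by the variant shifts", {
  cfg <- tracker_config()
  for (seed in 1:10) {
    w <- test_root_world(seed = seed, noise_sigma = 300)
    a <- max_intensity_project(
      render_view(w, list(x_um = 0, y_um = 0), c(96, 96), 1, time_h = 0), 1)
    b <- max_intensity_project(
      render_view(w, list(x_um = -3, y_um = -7), c(96, 96), 1, time_h = 0.01), 1)
    va <- filter_variants(a, cfg)
    vb <- filter_variants(b, cfg)
    shifts <- mapply(function(x, y) xcorr_shift(x, y), va, vb,
                     SIMPLIFY = FALSE)
    fused <- robust_shift(a, b, cfg)
    dxs <- vapply(shifts, `[[`, numeric(1), "dx_px")
    dys <- vapply(shifts, `[[`, numeric(1), "dy_px")
    expect_gte(fused$dx_px, min(dxs)); expect_lte(fused$dx_px, max(dxs))
    expect_gte(fused$dy_px, min(dys)); expect_lte(fused$dy_px, max(dys))
  }
})

test_that("displacement update applies pixel size and the axis map", {
  d0 <- displacement(0, 0)
  expect_equal(update_displacement(d0, lateral_shift(0, 0), 0.457),
               displacement(0, 0))

  d <- update_displacement(displacement(10, -5), lateral_shift(3, 2), 0.457)
  expect_equal(c(d$dx_um, d$dy_um), c(11.371, -4.086))

  # axis map flipping y leaves a zero y-component untouched
  d2 <- update_displacement(displacement(1, 1), lateral_shift(1, 0), 0.457,
                            axis_map(sy = -1))
  expect_equal(c(d2$dx_um, d2$dy_um), c(1.457, 1))

  # swap maps image columns onto stage y
  d3 <- update_displacement(displacement(0, 0), lateral_shift(2, 0), 1,
                            axis_map(swap_xy = TRUE))
  expect_equal(c(d3$dx_um, d3$dy_um), c(0, 2))

  expect_error(update_displacement(d0, lateral_shift(1, 1), 0), "pixel_size")
})

test_that("position prediction adds displacements to active specimens only", {
  pos <- stage_positions(c("a", "b"), x_um = c(100, 0), y_um = c(200, 0),
                         active = c(TRUE, FALSE))
  out <- predict_positions(pos, list(a = displacement(5, -2),
                                     b = displacement(999, 999)))
  expect_equal(out$x_um, c(105, 0))
  expect_equal(out$y_um, c(198, 0))

  # identity under zero displacement
  out0 <- predict_positions(pos, list(a = displacement(0, 0)))
  expect_equal(out0, pos)

  expect_error(predict_positions(pos, list(b = displacement(0, 0))),
               "missing displacement.*'a'")
})

test_that("displacement update and prediction compose linearly", {
  px <- 0.457
  pos <- stage_positions("a", 10, 20)
  s1 <- lateral_shift(3, -1); s2 <- lateral_shift(-2, 5)
  two_steps <- predict_positions(
    predict_positions(pos, list(a = update_displacement(displacement(), s1, px))),
    list(a = update_displacement(displacement(), s2, px)))
  combined <- predict_positions(
    pos, list(a = update_displacement(
      update_displacement(displacement(), s1, px), s2, px)))
  expect_equal(two_steps, combined)
})
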
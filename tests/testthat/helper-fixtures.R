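# Shared fixtures: all synthetic, built in code at test time.

# circular roll: content moves down by dr rows and right by dc cols
roll <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(p) - 1 - dc) %% p) + 1]
}

rand_texture <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# Independent oracle: direct cross-correlation of the mean-subtracted images
# by explicit summation over every integer lag, zero outside the overlap.
bf_xcorr <- function(ref, cur) {
  a <- ref - mean(ref)
  b <- cur - mean(cur)
  nr <- nrow(a); nc <- ncol(a)
  dy <- -(nr - 1):(nr - 1)
  dx <- -(nc - 1):(nc - 1)
  s <- matrix(0, length(dy), length(dx))
  for (i in seq_along(dy)) for (j in seq_along(dx)) {
    v <- dy[i]; u <- dx[j]
    rows <- max(1, 1 - v):min(nr, nr - v)
    cols <- max(1, 1 - u):min(nc, nc - u)
    s[i, j] <- sum(a[rows, cols] * b[rows + v, cols + u])
  }
  list(surface = s, dy_lags = dy, dx_lags = dx)
}

# small constant-speed root world for closed-loop tests
test_root_world <- function(speed = 150, noise_sigma = 0, seed = 1,
                            direction_deg = 0, start = c(0, 0), ...) {
  make_root_world(synthetic_root_spec(
    start_xy_um = start, direction_deg = direction_deg,
    speed_profile = data.frame(start_h = 0, end_h = Inf,
                               speed_um_per_h = speed),
    noise_sigma = noise_sigma, seed = seed, ...))
}

# cluster world whose centroid teleports by `jump` um (in y) at `jump_h`
teleport_cluster_world <- function(speed = 30, jump = 500, jump_h = 1,
                                   seed = 1) {
  make_cluster_world(
    centroid_path = function(t) c(0, speed * t + ifelse(t >= jump_h, jump, 0)),
    n_cells = 12, cell_radius_um = 60, spread_um = 150, jitter_um = 0,
    psf_sigma_px = 0.5, seed = seed)
}
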
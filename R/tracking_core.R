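#' Lateral shift and cumulative displacement
#'
#' A `lateral_shift` is the per-interval image-frame displacement of the
#' specimen relative to the previous acquisition, in pixels (column = dx,
#' row = dy, row increasing downward). A `displacement` is the stage-frame
#' estimate of the per-interval specimen motion in micrometres, the quantity
#' added to the current stage position to predict the next one.
#'
#' @param dx_px,dy_px signed shift in pixels.
#' @param dx_um,dy_um signed displacement in micrometres.
#' @return a `lateral_shift` / `displacement` object.
#' @export
lateral_shift <- function(dx_px = 0, dy_px = 0) {
  stopifnot(is.finite(dx_px), is.finite(dy_px))
  structure(list(dx_px = as.numeric(dx_px), dy_px = as.numeric(dy_px)),
            class = "lateral_shift")
}

#' @rdname lateral_shift
#' @export
displacement <- function(dx_um = 0, dy_um = 0) {
  stopifnot(is.finite(dx_um), is.finite(dy_um))
  structure(list(dx_um = as.numeric(dx_um), dy_um = as.numeric(dy_um)),
            class = "displacement")
}

#' Crop the centred tracking window from an image
#'
#' Returns the centred square window whose side is
#' `floor(roi_fraction * min(nrow, ncol))` pixels (at least 1).
#'
#' @param image numeric matrix.
#' @param roi_fraction fraction of the smaller image dimension, in (0, 1].
#' @return numeric matrix (the cropped window).
#' @export
crop_roi <- function(image, roi_fraction = 1 / 3) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (!is.finite(roi_fraction) || roi_fraction <= 0 || roi_fraction > 1)
    stop("roi_fraction must be in (0, 1]")
  side <- max(1L, floor(roi_fraction * min(dim(image))))
  r0 <- floor((nrow(image) - side) / 2)
  c0 <- floor((ncol(image) - side) / 2)
  image[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), drop = FALSE]
}

# centred square crop of the largest side <= min(dim) whose margin over
# `template_side` is even (keeps centre-aligned correlation lags integer)
crop_search_window <- function(image, template_side) {
  side <- min(dim(image))
  if ((side - template_side) %% 2L) side <- side - 1L
  r0 <- floor((nrow(image) - side) / 2)
  c0 <- floor((ncol(image) - side) / 2)
  image[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), drop = FALSE]
}

#' Filter variants of a tracking window
#'
#' Produces the three images whose pairwise shifts are fused by
#' [robust_shift()]: the raw image, a moving-average version and a
#' moving-median version. Borders are handled by edge replication, which
#' avoids spurious dark frames that would bias the correlation.
#'
#' @param image numeric matrix.
#' @param config a [tracker_config] supplying the (odd) kernel sides.
#' @return named list `raw`, `mean`, `median` of equal-size matrices.
#' @export
filter_variants <- function(image, config = tracker_config()) {
  if (!is.matrix(image)) stop("image must be a matrix")
  list(raw = image,
       mean = .mean_filter_cpp(image, config$mean_kernel_px),
       median = .median_filter_cpp(image, config$median_kernel_px))
}

#' Cross-correlation surface of a template against a search image
#'
#' Direct (amplitude-unnormalised) cross-correlation of the mean-subtracted
#' images over all lateral lags, evaluated with zero-padded FFTs. The
#' surface value at lag (dx, dy) is the sum over the overlap of
#' `ref(r, c) * cur(r + dy + oy, c + dx + ox)` with out-of-range pixels
#' treated as zero, where `(ox, oy)` aligns the two image centres; its peak
#' sits at the translation of `cur`'s content relative to `ref`.
#'
#' `cur` may be larger than `ref` (template matching): the tracking window
#' of the previous time point is then searched within a larger region of
#' the current frame, so that any displacement up to the window size keeps
#' the template fully overlapped instead of being penalised by the
#' shrinking overlap of two equal crops. Size differences must be even in
#' each dimension so that centre-aligned lags stay integer.
#'
#' @param ref template matrix (previous tracking window).
#' @param cur search matrix, same size as `ref` or larger.
#' @return list with `surface` (matrix indexed `[dy lag, dx lag]` in
#'   ascending lag order), `dy_lags` and `dx_lags` (signed integer lag
#'   vectors matching the surface rows/columns, centre-aligned convention).
#' @export
xcorr_surface <- function(ref, cur) {
  if (!is.matrix(ref) || !is.matrix(cur)) stop("inputs must be matrices")
  if (nrow(cur) < nrow(ref) || ncol(cur) < ncol(ref))
    stop(sprintf("dimension mismatch: search %dx%d smaller than template %dx%d",
                 nrow(cur), ncol(cur), nrow(ref), ncol(ref)))
  if ((nrow(cur) - nrow(ref)) %% 2L || (ncol(cur) - ncol(ref)) %% 2L)
    stop("template and search sizes must differ by an even margin")
  nr <- nrow(ref); nc <- ncol(ref)
  pr <- nrow(cur); pc <- ncol(cur)
  mr <- stats::nextn(nr + pr - 1L, c(2, 3, 5))
  mc <- stats::nextn(nc + pc - 1L, c(2, 3, 5))
  a <- matrix(0, mr, mc); a[1:nr, 1:nc] <- ref - mean(ref)
  b <- matrix(0, mr, mc); b[1:pr, 1:pc] <- cur - mean(cur)
  s <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / (mr * mc)
  # top-left-origin lags, then recentre so lag 0 aligns the image centres
  oy <- (pr - nr) %/% 2L
  ox <- (pc - nc) %/% 2L
  dy_tl <- -(nr - 1L):(pr - 1L)
  dx_tl <- -(nc - 1L):(pc - 1L)
  surf <- s[(dy_tl %% mr) + 1L, (dx_tl %% mc) + 1L, drop = FALSE]
  list(surface = surf, dy_lags = dy_tl - oy, dx_lags = dx_tl - ox)
}

#' Lateral shift from the cross-correlation peak
#'
#' Locates the maximum of the cross-correlation surface of the two
#' mean-subtracted images. The returned shift moves `ref`'s content onto
#' `cur`'s: `cur` content displaced by +shift relative to `ref`. Ties at the
#' peak are broken toward the smaller shift magnitude, then toward
#' non-negative dx, then non-negative dy. With `subpixel = TRUE` the integer
#' peak is refined by parabolic interpolation through the peak and its four
#' neighbours.
#'
#' @param ref template matrix (previous tracking window), nonzero variance.
#' @param cur search matrix, same size or larger (see [xcorr_surface()]),
#'   nonzero variance.
#' @param subpixel refine the peak to sub-pixel precision.
#' @return a [lateral_shift].
#' @export
xcorr_shift <- function(ref, cur, subpixel = FALSE) {
  for (nm in c("ref", "cur")) {
    img <- get(nm)
    if (sd(img) == 0)
      stop("zero-variance ", nm, " image: frame is untrackable")
  }
  xs <- xcorr_surface(ref, cur)
  s <- xs$surface
  mx <- max(s)
  tol <- 1e-9 * max(1, max(abs(s)))
  cand <- which(s >= mx - tol, arr.ind = TRUE)
  dy <- xs$dy_lags[cand[, 1]]
  dx <- xs$dx_lags[cand[, 2]]
  ord <- order(dx^2 + dy^2, dx < 0, dy < 0, -dx, -dy)
  pick <- ord[1]
  best <- c(cand[pick, 1], cand[pick, 2])
  dx0 <- dx[pick]
  dy0 <- dy[pick]
  if (!subpixel) return(lateral_shift(dx_px = dx0, dy_px = dy0))

  refine <- function(sm1, s0, sp1) {
    den <- sm1 - 2 * s0 + sp1
    if (den >= 0) return(0)                 # degenerate (flat/valley) peak
    off <- 0.5 * (sm1 - sp1) / den
    max(-0.5, min(0.5, off))
  }
  nr <- nrow(s); nc <- ncol(s)
  ddx <- ddy <- 0
  if (best[1] > 1 && best[1] < nr)          # no refinement at extreme lags
    ddy <- refine(s[best[1] - 1, best[2]], s[best[1], best[2]],
                  s[best[1] + 1, best[2]])
  if (best[2] > 1 && best[2] < nc)
    ddx <- refine(s[best[1], best[2] - 1], s[best[1], best[2]],
                  s[best[1], best[2] + 1])
  lateral_shift(dx_px = dx0 + ddx, dy_px = dy0 + ddy)
}

#' Robust median-of-three shift estimate
#'
#' Estimates the shift independently on the raw, mean-filtered and
#' median-filtered variants of the two images and returns the
#' component-wise median of the three results, which discards a single
#' outlying variant estimate (e.g. a noise-driven spurious peak on the raw
#' pair).
#'
#' @param ref template matrix (previous tracking window).
#' @param cur search matrix, same size or larger (see [xcorr_surface()]).
#' @param config a [tracker_config].
#' @return a [lateral_shift].
#' @export
robust_shift <- function(ref, cur, config = tracker_config()) {
  vr <- filter_variants(ref, config)
  vc <- filter_variants(cur, config)
  shifts <- mapply(function(a, b) xcorr_shift(a, b, subpixel = config$subpixel),
                   vr, vc, SIMPLIFY = FALSE)
  lateral_shift(
    dx_px = median(vapply(shifts, `[[`, numeric(1), "dx_px")),
    dy_px = median(vapply(shifts, `[[`, numeric(1), "dy_px")))
}

#' Update the cumulative displacement from a measured shift
#'
#' The displacement recurrence delta(t) = delta(t-1) + shift * pixel_size:
#' because each frame is acquired after the stage already applied the
#' previous prediction, the measured shift is the residual prediction error
#' and the recurrence converges to the specimen's per-interval motion.
#'
#' @param prev previous [displacement] (micrometres).
#' @param shift measured [lateral_shift] (pixels).
#' @param pixel_size micrometres per pixel (> 0).
#' @param axis_map an [axis_map] relating image axes to stage axes.
#' @return updated [displacement].
#' @export
update_displacement <- function(prev, shift, pixel_size,
                                axis_map = tiptrace::axis_map()) {
  stopifnot(inherits(prev, "displacement"), inherits(shift, "lateral_shift"))
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  v <- apply_axis_map(c(shift$dx_px, shift$dy_px) * pixel_size, axis_map)
  displacement(dx_um = prev$dx_um + v[1], dy_um = prev$dy_um + v[2])
}

#' Predict the next stage positions
#'
#' Advances every active specimen's stage position by its displacement:
#' P(t+1) = P(t) + delta(t). Inactive specimens keep their last position
#' verbatim; z passes through unchanged.
#'
#' @param positions stage-position data frame (see [stage_positions()]).
#' @param displacements named list of [displacement] objects keyed by
#'   `specimen_id`; every active specimen must have an entry.
#' @return the updated stage-position data frame.
#' @export
predict_positions <- function(positions, displacements) {
  positions <- validate_positions(positions)
  for (i in seq_len(nrow(positions))) {
    if (!positions$active[i]) next
    id <- positions$specimen_id[i]
    d <- displacements[[id]]
    if (is.null(d))
      stop("missing displacement for active specimen '", id, "'")
    positions$x_um[i] <- positions$x_um[i] + d$dx_um
    positions$y_um[i] <- positions$y_um[i] + d$dy_um
  }
  positions
}
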
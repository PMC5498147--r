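#' Write / read a multi-position time-point file
#'
#' One acquisition time point is stored as a single multi-page 16-bit TIFF
#' holding the z-stacks of all positions, page order
#' position -> channel -> z (slowest to fastest). Acquisition metadata
#' (dimension order, pixel size, time, specimen ids) travels in a JSON
#' sidecar `<path>.json`, since baseline TIFF has no portable hyperstack
#' tags. Round trips are lossless.
#'
#' @param stacks list of [frame_stack]s, one per position, sharing pixel
#'   size, frame dimensions and channel/z counts.
#' @param path output TIFF path (`.tif`).
#' @return `read_timepoint` returns the list of [frame_stack]s, named by
#'   specimen id.
#' @export
write_timepoint <- function(stacks, path) {
  stopifnot(length(stacks) >= 1)
  dims <- lapply(stacks, function(s) dim(s$intensities))
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) all(d == d0), logical(1))))
    stop("inconsistent stack dimensions across positions")
  px <- vapply(stacks, `[[`, numeric(1), "pixel_size")
  if (length(unique(px)) != 1)
    stop("inconsistent pixel size across positions")
  if (any(vapply(stacks, function(s) max(s$intensities), numeric(1)) > 65535))
    stop("intensities exceed the 16-bit range")

  pages <- list()
  for (s in stacks) for (ch in seq_len(d0[1])) for (z in seq_len(d0[2])) {
    pages[[length(pages) + 1L]] <-
      matrix(s$intensities[ch, z, , ], d0[3], d0[4]) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    dimension_order = "position,channel,z,row,col",
    n_position = length(stacks), n_channel = d0[1], n_z = d0[2],
    rows = d0[3], cols = d0[4],
    pixel_size_um = px[1],
    time_index = stacks[[1]]$time_index, time_h = stacks[[1]]$time_h,
    specimen_ids = vapply(stacks, `[[`, character(1), "specimen_id"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_timepoint
#' @export
read_timepoint <- function(path) {
  if (!file.exists(path)) stop("unreadable time-point file: ", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  np <- meta$n_position; nc <- meta$n_channel; nz <- meta$n_z
  if (length(pages) != np * nc * nz)
    stop(sprintf("page count %d does not match metadata (%d x %d x %d)",
                 length(pages), np, nc, nz))
  k <- 0L
  out <- list()
  for (p in seq_len(np)) {
    arr <- array(0, dim = c(nc, nz, meta$rows, meta$cols))
    for (ch in seq_len(nc)) for (z in seq_len(nz)) {
      k <- k + 1L
      arr[ch, z, , ] <- pages[[k]]
    }
    out[[meta$specimen_ids[p]]] <- frame_stack(
      arr, pixel_size = meta$pixel_size_um, time_index = meta$time_index,
      time_h = meta$time_h, specimen_id = meta$specimen_ids[p])
  }
  out
}

#' Split per-time-point multi-position files into per-position hyperstacks
#'
#' Converts an ordered series of multi-position time-point files into one
#' hyperstack file per position, page order time -> channel -> z, with
#' voxel data bit-identical to the sources and time order preserved.
#'
#' @param timepoint_files character vector of time-point TIFF paths in
#'   acquisition order.
#' @param out_dir output directory (created if absent).
#' @return named character vector of written per-position hyperstack paths.
#' @export
split_by_position <- function(timepoint_files, out_dir) {
  stopifnot(length(timepoint_files) >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  series <- lapply(timepoint_files, read_timepoint)
  ids <- names(series[[1]])
  for (i in seq_along(series)) {
    if (!identical(names(series[[i]]), ids))
      stop("inconsistent position set in file: ", timepoint_files[i])
  }
  out <- character(0)
  for (id in ids) {
    stacks <- lapply(series, `[[`, id)
    d0 <- dim(stacks[[1]]$intensities)
    pages <- list()
    for (s in stacks) for (ch in seq_len(d0[1])) for (z in seq_len(d0[2])) {
      pages[[length(pages) + 1L]] <-
        matrix(s$intensities[ch, z, , ], d0[3], d0[4]) / 65535
    }
    path <- file.path(out_dir, paste0("position_", id, ".tif"))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    meta <- list(
      dimension_order = "time,channel,z,row,col",
      n_time = length(stacks), n_channel = d0[1], n_z = d0[2],
      rows = d0[3], cols = d0[4],
      pixel_size_um = stacks[[1]]$pixel_size,
      specimen_id = id,
      time_index = vapply(stacks, `[[`, integer(1), "time_index"),
      time_h = vapply(stacks, `[[`, numeric(1), "time_h"))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out[id] <- path
  }
  out
}

#' Read a per-position hyperstack written by [split_by_position()]
#'
#' @param path hyperstack TIFF path.
#' @return list of [frame_stack]s in time order (one per time point).
#' @export
read_hyperstack <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("unreadable hyperstack: ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nt <- meta$n_time; nc <- meta$n_channel; nz <- meta$n_z
  if (length(pages) != nt * nc * nz)
    stop("page count does not match hyperstack metadata: ", path)
  k <- 0L
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    arr <- array(0, dim = c(nc, nz, meta$rows, meta$cols))
    for (ch in seq_len(nc)) for (z in seq_len(nz)) {
      k <- k + 1L
      arr[ch, z, , ] <- pages[[k]]
    }
    out[[t]] <- frame_stack(arr, pixel_size = meta$pixel_size_um,
                            time_index = meta$time_index[t],
                            time_h = meta$time_h[t],
                            specimen_id = meta$specimen_id)
  }
  out
}
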
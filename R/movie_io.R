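#' Construct a calcium-imaging recording movie
#'
#' A recording movie is the raw substrate of the fingerprint pipeline: a stack
#' of fluorescence frames plus the acquisition and stimulation metadata needed
#' to interpret it (frame rate, pixel size, stimulation epochs, electrode
#' position, and the oral direction of the gut axis).
#'
#' Frame indices are 1-based and inclusive. Stimulation epochs must be ordered,
#' non-overlapping and lie within the movie. All spatial metadata is in um;
#' pixel-to-um conversion happens once, at read/construction time.
#'
#' @param frames Numeric array `H x W x T` of non-negative intensities (counts).
#' @param frame_rate_hz Acquisition rate (Hz).
#' @param pixel_size_um Pixel pitch (um/pixel).
#' @param stim_epochs Data frame with columns `start_frame`, `end_frame`
#'   (1-based, inclusive) and optionally `label`, `pulse_width_us`, `freq_hz`,
#'   `duration_s` describing each electrical stimulus train.
#' @param electrode_xy Electrode position, um, length-2 `(x, y)`.
#' @param oral_axis Unit vector (length 2) pointing in the oral direction.
#' @return A `recording_movie` object.
#' @export
recording_movie <- function(frames, frame_rate_hz, pixel_size_um, stim_epochs,
                            electrode_xy, oral_axis) {
  if (length(dim(frames)) != 3) stop("frames must be an H x W x T array")
  tn <- dim(frames)[3]
  if (tn < 1) stop("movie must have at least one frame")
  if (any(frames < 0)) stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) stop("frame_rate_hz must be > 0")
  stim_epochs <- tibble::as_tibble(stim_epochs)
  if (!all(c("start_frame", "end_frame") %in% names(stim_epochs))) {
    stop("stim_epochs needs start_frame and end_frame columns")
  }
  if (nrow(stim_epochs)) {
    with(stim_epochs, {
      if (any(start_frame < 1 | end_frame > tn)) stop("stim epochs must lie within [1, T]")
      if (any(end_frame < start_frame)) stop("stim epochs must have end_frame >= start_frame")
      if (is.unsorted(start_frame, strictly = TRUE)) stop("stim epochs must be ordered")
      if (nrow(stim_epochs) > 1 &&
          any(start_frame[-1] <= end_frame[-nrow(stim_epochs)])) {
        stop("stim epochs must not overlap")
      }
    })
  }
  if (length(electrode_xy) != 2) stop("electrode_xy must have length 2")
  if (length(oral_axis) != 2 || sum(oral_axis^2) == 0) stop("oral_axis must be a non-zero 2-vector")
  oral_axis <- oral_axis / sqrt(sum(oral_axis^2))
  structure(list(
    frames = frames,
    frame_rate_hz = as.numeric(frame_rate_hz),
    pixel_size_um = as.numeric(pixel_size_um),
    stim_epochs = stim_epochs,
    electrode_xy = as.numeric(electrode_xy),
    oral_axis = as.numeric(oral_axis)
  ), class = "recording_movie")
}

#' @export
print.recording_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<recording_movie> %d x %d px, %d frames @ %g Hz, %g um/px, %d stim epoch(s)\n",
    d[1], d[2], d[3], x$frame_rate_hz, x$pixel_size_um, nrow(x$stim_epochs)
  ))
  invisible(x)
}

movie_meta_keys <- c("frame_rate_hz", "pixel_size_um", "stim_epochs",
                     "electrode_xy", "oral_axis")

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

#' Write a recording movie as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 16-bit unsigned integers (values are clamped to
#' `[0, 65535]` and rounded); metadata goes into a `<stem>.meta.json` sidecar
#' next to the TIFF. Integer-valued frames round-trip exactly.
#'
#' @param movie A `recording_movie`.
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "recording_movie"))
  tn <- dim(movie$frames)[3]
  pages <- lapply(seq_len(tn), function(t) {
    pmin(pmax(round(movie$frames[, , t]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(
    frame_rate_hz = movie$frame_rate_hz,
    pixel_size_um = movie$pixel_size_um,
    stim_epochs = movie$stim_epochs,
    electrode_xy = movie$electrode_xy,
    oral_axis = movie$oral_axis
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording movie from disk
#'
#' Reads a multi-page TIFF movie written by [write_movie()] (or any 16-bit
#' multi-page TIFF) together with its `<stem>.meta.json` metadata sidecar.
#' Every required metadata key is checked and named individually on error.
#'
#' @param path Path to the `.tif`/`.tiff` movie.
#' @return A `recording_movie`.
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("metadata sidecar not found: ", sp)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- vapply(pages, function(p) round(p * 65535), matrix(0, nrow(pages[[1]]), ncol(pages[[1]])))
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1L)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (k in movie_meta_keys) {
    if (is.null(meta[[k]])) stop("movie metadata missing required key: ", k)
  }
  recording_movie(frames,
    frame_rate_hz = meta$frame_rate_hz,
    pixel_size_um = meta$pixel_size_um,
    stim_epochs = meta$stim_epochs,
    electrode_xy = meta$electrode_xy,
    oral_axis = meta$oral_axis
  )
}

#' Write and read result tables
#'
#' Thin CSV wrappers with a stable column order and full numeric precision.
#' An empty table is written as a header-only CSV.
#'
#' @param records A data frame (possibly zero-row).
#' @param path Output CSV path.
#' @return `write_table()` returns `path` invisibly; `read_table()` a tibble.
#' @export
write_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write and read 3D binary masks as multi-page TIFF
#'
#' Each z-slice becomes one TIFF page; voxels are 0/1.
#'
#' @param mask Logical or 0/1 numeric 3D array (`x, y, z`).
#' @param path Output `.tif` path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` a logical
#'   3D array.
#' @export
write_mask <- function(mask, path) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array")
  pages <- lapply(seq_len(dim(mask)[3]), function(z) (mask[, , z] != 0) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) p > 0.5, matrix(TRUE, nrow(pages[[1]]), ncol(pages[[1]])))
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  arr
}
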
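#' Pixels covered by an elliptical ROI
#'
#' ROIs are axis-aligned ellipses specified in um by their center and full
#' axis lengths (diameters). A pixel belongs to the ROI when its center lies
#' inside or on the ellipse boundary (boundary ties included).
#'
#' @param roi One-row data frame / list with `cx_um`, `cy_um`, `long_um`,
#'   `short_um` (long axis along x, the gut axis).
#' @param dim_hw Movie frame dimensions `c(H, W)` in pixels.
#' @param pixel_size_um Pixel pitch (um).
#' @return Integer matrix with columns `row`, `col` of covered pixels.
#' @keywords internal
roi_pixels <- function(roi, dim_hw, pixel_size_um) {
  a <- roi$long_um / 2
  b <- roi$short_um / 2
  # pixel (r, c) has center ((c - 0.5) * px, (r - 0.5) * px) in (x, y) um
  cmin <- max(1L, floor((roi$cx_um - a) / pixel_size_um))
  cmax <- min(dim_hw[2], ceiling((roi$cx_um + a) / pixel_size_um) + 1L)
  rmin <- max(1L, floor((roi$cy_um - b) / pixel_size_um))
  rmax <- min(dim_hw[1], ceiling((roi$cy_um + b) / pixel_size_um) + 1L)
  if (cmin > cmax || rmin > rmax) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  rr <- rmin:rmax
  cc <- cmin:cmax
  g <- expand.grid(row = rr, col = cc)
  x <- (g$col - 0.5) * pixel_size_um
  y <- (g$row - 0.5) * pixel_size_um
  inside <- ((x - roi$cx_um) / a)^2 + ((y - roi$cy_um) / b)^2 <= 1
  as.matrix(g[inside, , drop = FALSE])
}

#' Extract the raw fluorescence trace of one ROI
#'
#' The trace value at frame t is the mean intensity over all pixels whose
#' centers fall inside the ROI ellipse.
#'
#' @param movie A [recording_movie()].
#' @param roi One-row ROI (see [roi_pixels()]).
#' @return Numeric vector of length T (counts per frame).
#' @export
extract_trace <- function(movie, roi) {
  stopifnot(inherits(movie, "recording_movie"))
  d <- dim(movie$frames)
  px <- roi_pixels(roi, d[1:2], movie$pixel_size_um)
  if (nrow(px) == 0) stop("ROI ", roi$id %||% "?", " covers no pixel in the field")
  flat <- matrix(movie$frames, d[1] * d[2], d[3])
  idx <- px[, "row"] + (px[, "col"] - 1L) * d[1]
  colMeans(flat[idx, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a raw trace to its baseline starting value
#'
#' F0 is the mean of the raw trace over the baseline window; the normalized
#' trace is `raw / F0` (so a resting trace sits at 1.0 and amplitudes are in
#' dF/F0 units).
#'
#' @param raw Numeric trace (counts).
#' @param baseline_window Integer frame indices of the baseline window.
#' @return List with `f0` and `trace_norm`.
#' @export
normalize_dff <- function(raw, baseline_window) {
  if (length(baseline_window) == 0) stop("baseline window is empty")
  if (any(baseline_window < 1 | baseline_window > length(raw))) {
    stop("baseline window outside the trace")
  }
  f0 <- mean(raw[baseline_window])
  if (!is.finite(f0) || f0 <= 0) stop("baseline fluorescence F0 must be > 0")
  list(f0 = f0, trace_norm = raw / f0)
}

#' Calcium transient amplitude (dF/F0)
#'
#' Amplitude is the difference between the maximal normalized fluorescence in
#' the response window and the mean normalized fluorescence in the baseline
#' window. The response window starts at the stimulus epoch onset and lasts
#' `response_window_s` seconds, clipped to the movie length. Non-responders
#' can yield amplitudes at or below zero.
#'
#' @param trace_norm Normalized trace (F_i/F0).
#' @param baseline_window Integer frame indices of the baseline window.
#' @param stim_start 1-based frame index of the stimulus onset.
#' @param response_window_s Response window length (s).
#' @param frame_rate_hz Frame rate (Hz).
#' @return Amplitude (dF/F0, unitless).
#' @export
transient_amplitude <- function(trace_norm, baseline_window, stim_start,
                                response_window_s, frame_rate_hz) {
  tn <- length(trace_norm)
  if (stim_start > tn) stop("stimulus epoch starts beyond the end of the movie")
  last <- min(tn, stim_start + ceiling(response_window_s * frame_rate_hz) - 1L)
  win <- stim_start:last
  if (length(win) == 0) stop("response window is empty after clipping")
  max(trace_norm[win]) - mean(trace_norm[baseline_window])
}

#' Responder criterion
#'
#' A neuron responded to a stimulus when its transient amplitude exceeds both
#' an absolute floor and `k` times the baseline noise of its normalized trace.
#'
#' @param amplitude dF/F0 amplitude.
#' @param baseline_noise_sd SD of the normalized trace over the baseline
#'   window (>= 0).
#' @param k Noise multiplier (default 5).
#' @param floor Absolute dF/F0 floor (default 0.05).
#' @return Logical.
#' @export
detect_responder <- function(amplitude, baseline_noise_sd, k = 5, floor = 0.05) {
  if (any(baseline_noise_sd < 0)) stop("baseline_noise_sd must be >= 0")
  amplitude > pmax(floor, k * baseline_noise_sd)
}

#' Per-neuron, per-stimulus responses for a whole movie
#'
#' Runs trace extraction, baseline normalization, amplitude measurement and
#' the responder criterion for every ROI and every stimulation epoch. Each
#' epoch uses its own baseline window (the `baseline_frames` frames preceding
#' the epoch onset), so slow drift between stimulations does not bias the
#' amplitude ratio.
#'
#' @param movie A [recording_movie()].
#' @param rois ROI table with columns `id`, `cx_um`, `cy_um`, `long_um`,
#'   `short_um` (and optionally `ganglion_id`).
#' @param config A [run_config()].
#' @return Tibble with columns `roi_id`, `stim_index`, `f0`, `amplitude`,
#'   `baseline_sd`, `responded`.
#' @export
compute_responses <- function(movie, rois, config = run_config()) {
  stopifnot(inherits(movie, "recording_movie"))
  rois <- tibble::as_tibble(rois)
  epochs <- movie$stim_epochs
  if (nrow(epochs) == 0) stop("movie has no stimulation epochs")
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, d[1] * d[2], d[3])  # flatten once for all ROIs
  out <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    px <- roi_pixels(roi, d[1:2], movie$pixel_size_um)
    if (nrow(px) == 0) stop("ROI ", roi$id, " covers no pixel in the field")
    raw <- colMeans(flat[px[, "row"] + (px[, "col"] - 1L) * d[1], , drop = FALSE])
    per_epoch <- lapply(seq_len(nrow(epochs)), function(e) {
      s <- epochs$start_frame[e]
      bw <- max(1L, s - config$baseline_frames):(s - 1L)
      nd <- normalize_dff(raw, bw)
      amp <- transient_amplitude(nd$trace_norm, bw, s,
                                 config$response_window_s, movie$frame_rate_hz)
      bsd <- stats::sd(nd$trace_norm[bw])
      tibble::tibble(
        roi_id = roi$id, stim_index = e, f0 = nd$f0, amplitude = amp,
        baseline_sd = bsd,
        responded = detect_responder(amp, bsd, config$responder_k,
                                     config$responder_floor)
      )
    })
    out[[i]] <- dplyr::bind_rows(per_epoch)
  }
  dplyr::bind_rows(out)
}
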
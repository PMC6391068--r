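#' Configuration of the synthetic calcium-imaging movie generator
#'
#' The generator emulates the statistical structure the fingerprint pipeline
#' assumes: a field of myenteric ganglia imaged at 2 Hz, two electrical
#' stimulation epochs, stimulus-locked GCaMP-like transients with an
#' instantaneous rise and exponential decay, per-class amplitude ratios that
#' realize the five signature classes, and an optional class-specific aboral
#' placement bias relative to the electrode at the field center.
#'
#' The per-class amplitude laws are free parameters of the generator (real
#' per-class amplitude distributions are not known); defaults center the first
#' amplitude on 0.40 dF/F0 and keep the true ratios of Types II/III/IV well
#' inside their class intervals (0, 0.8), [0.8, 1.2] and (1.2, Inf).
#'
#' @param field_um Field size `(x, y)` in um; x is the gut (axial) direction.
#' @param pixel_size_um Pixel pitch (um).
#' @param frame_rate_hz Frame rate (Hz).
#' @param n_ganglia Number of ganglion centers in the field.
#' @param neurons_per_ganglion Average neurons per ganglion; the total neuron
#'   count is `n_ganglia * neurons_per_ganglion`.
#' @param soma_area_mean_um2,soma_area_sdlog Lognormal soma-area law
#'   (calibrated so the mean is ~170-185 um^2 by default).
#' @param aspect_range Range of soma long/short axis ratios.
#' @param class_props Named proportions of Types I-V; must sum to 1.
#' @param amp_mean,amp_sd,amp_range Truncated-normal law of the reference
#'   (first-response) amplitude in dF/F0 units.
#' @param ratio_ranges Named list of uniform true-ratio ranges for Types
#'   II, III and IV.
#' @param p_aboral Named per-class probability that a neuron lies aboral to
#'   the electrode.
#' @param tau_s Transient decay time constant (s).
#' @param stim_duration_s Stimulus train duration (s).
#' @param gap_s Gap between the two stimulus onsets (s); compressed relative
#'   to experimental inter-stimulus intervals since only the per-epoch
#'   statistics matter.
#' @param baseline_frames Frames recorded before the first stimulus.
#' @param tail_frames Frames recorded after the second stimulus onset.
#' @param noise_sd Additive Gaussian pixel noise, i.i.d. per pixel and frame,
#'   in baseline-normalized units (0 = noise-free).
#' @param gain_counts uint16 counts corresponding to normalized baseline 1.0.
#' @param background_counts Background level (counts).
#' @param condition_pair Label attached to generated signature truth.
#' @return A `sim_movie_config` list.
#' @export
sim_movie_config <- function(field_um = c(1700, 1300),
                             pixel_size_um = 5,
                             frame_rate_hz = 2,
                             n_ganglia = 30,
                             neurons_per_ganglion = 2,
                             soma_area_mean_um2 = 175,
                             soma_area_sdlog = 0.35,
                             aspect_range = c(1.1, 1.7),
                             class_props = c(I = 0.05, II = 0.20, III = 0.50,
                                             IV = 0.20, V = 0.05),
                             amp_mean = 0.40,
                             amp_sd = 0.05,
                             amp_range = c(0.25, 0.60),
                             ratio_ranges = list(II = c(0.35, 0.65),
                                                 III = c(0.90, 1.10),
                                                 IV = c(1.35, 1.90)),
                             p_aboral = c(I = 0.9, II = 0.5, III = 0.5,
                                          IV = 0.5, V = 0.5),
                             tau_s = 2,
                             stim_duration_s = 2,
                             gap_s = 60,
                             baseline_frames = 10,
                             tail_frames = 30,
                             noise_sd = 0,
                             gain_counts = 1000,
                             background_counts = 100,
                             condition_pair = "Ctrl-Ctrl") {
  cfg <- as.list(environment())
  if (abs(sum(class_props) - 1) > 1e-9) stop("class proportions must sum to 1")
  if (!all(c("I", "II", "III", "IV", "V") %in% names(class_props))) {
    stop("class_props must name Types I-V")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  gap_frames <- round(gap_s * frame_rate_hz)
  if (gap_frames <= ceiling(stim_duration_s * frame_rate_hz)) {
    stop("stimulation epochs overlap: increase gap_s")
  }
  class(cfg) <- "sim_movie_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < range[1] | x > range[2])
  }
  x
}

#' Generate the cellular layout and ground-truth fingerprint of a movie
#'
#' Draws soma positions, sizes, classes and true amplitudes without rendering
#' any pixels. Positions follow the spatial-bias model: per neuron a Bernoulli
#' draw on the sign of the axial (oral-aboral) offset relative to the central
#' electrode, magnitude uniform over the field; somas are rejected until they
#' do not overlap. Used by [generate_movie()] and directly whenever only the
#' ground truth geometry is needed.
#'
#' @param config A [sim_movie_config()].
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @return A `ground_truth` list: `rois` (tibble with `id`, `cx_um`, `cy_um`,
#'   `long_um`, `short_um`, `ganglion_id`, `soma_area_um2`, `cls`, `amp_es1`,
#'   `amp_es2`, `true_ratio`, `brightness`), `electrode_xy`, `oral_axis`,
#'   `class_props`, `p_aboral`, `condition_pair`, `seed`.
#' @export
generate_layout <- function(config = sim_movie_config(), seed = 1) {
  stopifnot(inherits(config, "sim_movie_config"))
  set.seed(seed)
  n <- config$n_ganglia * config$neurons_per_ganglion
  fx <- config$field_um[1]; fy <- config$field_um[2]
  electrode <- c(fx, fy) / 2

  cls <- sample(names(config$class_props), n, replace = TRUE,
                prob = config$class_props)
  area <- stats::rlnorm(n,
    meanlog = log(config$soma_area_mean_um2) - config$soma_area_sdlog^2 / 2,
    sdlog = config$soma_area_sdlog)
  aspect <- stats::runif(n, config$aspect_range[1], config$aspect_range[2])
  long <- sqrt(4 * area * aspect / pi)
  short <- long / aspect

  # spatial placement: Bernoulli sign of the axial offset, uniform magnitude
  cx <- cy <- numeric(n)
  margin <- long / 2 + config$pixel_size_um
  for (i in seq_len(n)) {
    # the aboral/oral sign is drawn once per neuron; collisions resample only
    # the position within the chosen half, so crowding cannot bias the sign
    sign_ab <- if (stats::runif(1) < config$p_aboral[[cls[i]]]) 1 else -1
    attempts <- 0
    repeat {
      attempts <- attempts + 1
      if (attempts > 1000) stop("field too crowded to place non-overlapping somas")
      ax <- sign_ab * stats::runif(1, 0, fx / 2 - margin[i])
      x <- electrode[1] + ax
      y <- stats::runif(1, margin[i], fy - margin[i])
      if (i == 1) break
      j <- seq_len(i - 1)
      sep <- sqrt((cx[j] - x)^2 + (cy[j] - y)^2)
      if (all(sep > (long[j] + long[i]) / 2 + config$pixel_size_um)) break
    }
    cx[i] <- x; cy[i] <- y
  }

  # ganglion centers on a jittered grid; membership by nearest center
  ng <- config$n_ganglia
  gx <- stats::runif(ng, 0, fx); gy <- stats::runif(ng, 0, fy)
  ganglion_id <- vapply(seq_len(n), function(i) {
    which.min((gx - cx[i])^2 + (gy - cy[i])^2)
  }, integer(1))

  amp_ref <- rtrunc_norm(n, config$amp_mean, config$amp_sd, config$amp_range)
  ratio <- rep(NA_real_, n)
  for (k in c("II", "III", "IV")) {
    m <- cls == k
    ratio[m] <- stats::runif(sum(m), config$ratio_ranges[[k]][1],
                             config$ratio_ranges[[k]][2])
  }
  amp_es1 <- ifelse(cls == "V", 0, amp_ref)
  amp_es2 <- dplyr::case_when(
    cls == "I" ~ 0,
    cls == "V" ~ amp_ref,
    TRUE ~ amp_ref * ratio
  )

  rois <- tibble::tibble(
    id = seq_len(n),
    cx_um = cx, cy_um = cy,
    long_um = long, short_um = short,
    ganglion_id = ganglion_id,
    soma_area_um2 = ellipse_area(long, short),
    cls = factor(cls, levels = c("I", "II", "III", "IV", "V")),
    amp_es1 = amp_es1, amp_es2 = amp_es2, true_ratio = ratio,
    brightness = config$gain_counts * stats::runif(n, 0.8, 1.2)
  )
  structure(list(
    rois = rois,
    electrode_xy = electrode,
    oral_axis = c(-1, 0),
    class_props = config$class_props,
    p_aboral = config$p_aboral,
    condition_pair = config$condition_pair,
    seed = seed
  ), class = "ground_truth")
}

#' Generate a synthetic two-stimulus calcium-imaging movie with ground truth
#'
#' Renders the [generate_layout()] somas as filled ellipses of per-neuron
#' uniform brightness, adds stimulus-locked transients (normalized amplitude
#' times an instantaneous-rise/exponential-decay kernel on a baseline of 1.0,
#' scaled to uint16 counts), and additive i.i.d. Gaussian pixel noise. Type I
#' neurons have a zero second-stimulus transient, Type V a zero first one.
#' The returned ground truth contains the exact rendered ROI table.
#'
#' @inheritParams generate_layout
#' @return List with `movie` (a [recording_movie()]) and `truth`
#'   (a `ground_truth`).
#' @export
generate_movie <- function(config = sim_movie_config(), seed = 1) {
  truth <- generate_layout(config, seed)
  fps <- config$frame_rate_hz
  train_frames <- ceiling(config$stim_duration_s * fps)
  es1 <- config$baseline_frames + 1L
  es2 <- es1 + as.integer(round(config$gap_s * fps))
  tn <- es2 + config$tail_frames - 1L
  hh <- ceiling(config$field_um[2] / config$pixel_size_um)
  ww <- ceiling(config$field_um[1] / config$pixel_size_um)

  rois <- truth$rois
  px <- lapply(seq_len(nrow(rois)), function(i) {
    p <- roi_pixels(rois[i, ], c(hh, ww), config$pixel_size_um)
    p[, "row"] + (p[, "col"] - 1L) * hh
  })

  tt <- seq_len(tn)
  kern <- function(onset) ifelse(tt >= onset, exp(-((tt - onset) / fps) / config$tau_s), 0)
  k1 <- kern(es1); k2 <- kern(es2)

  frames <- array(0, dim = c(hh, ww, tn))
  base_img <- matrix(config$background_counts, hh, ww)
  for (i in seq_len(nrow(rois))) base_img[px[[i]]] <- rois$brightness[i]
  npx <- hh * ww
  for (t in tt) {
    img <- base_img
    for (i in seq_len(nrow(rois))) {
      a <- rois$amp_es1[i] * k1[t] + rois$amp_es2[i] * k2[t]
      if (a > 0) img[px[[i]]] <- rois$brightness[i] * (1 + a)
    }
    if (config$noise_sd > 0) {
      img <- img + stats::rnorm(npx, 0, config$noise_sd * config$gain_counts)
    }
    frames[, , t] <- pmin(pmax(round(img), 0), 65535)
  }

  epochs <- tibble::tibble(
    start_frame = c(es1, es2),
    end_frame = c(es1 + train_frames - 1L, es2 + train_frames - 1L),
    label = c("ES1", "ES2"),
    pulse_width_us = 300, freq_hz = 20,
    duration_s = config$stim_duration_s
  )
  movie <- recording_movie(frames, fps, config$pixel_size_um, epochs,
                           truth$electrode_xy, truth$oral_axis)
  list(movie = movie, truth = truth)
}

#' Pixel noise level for a target per-pixel signal-to-noise ratio
#'
#' Returns the `noise_sd` (baseline-normalized units) at which the mean
#' reference amplitude over the pixel noise SD equals `snr`. ROI-mean traces
#' then have a noise SD roughly `sqrt(Npx)`-fold smaller, where `Npx` is the
#' soma pixel count.
#'
#' @param config A [sim_movie_config()].
#' @param snr Target per-pixel SNR.
#' @return Noise SD in normalized units.
#' @export
noise_sd_for_snr <- function(config, snr) {
  if (snr <= 0) stop("snr must be > 0")
  config$amp_mean / snr
}

#' Serialize ground truth alongside generated data
#'
#' @param truth A `ground_truth` object.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       factor = "string")
  invisible(path)
}
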
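#' Configuration of the synthetic motility-map generator
#'
#' Emulates a spatiotemporal diameter map of the isolated colon: a constant
#' baseline diameter interrupted by contraction bands that initiate at the
#' oral end at a configured rate and propagate aborally at constant speed.
#'
#' Events are scheduled quasi-regularly: `round(rate * duration)` onsets at
#' the expected spacing with uniform jitter, so the generated event count
#' equals the configured rate times the duration (to rounding), which is what
#' a frequency-recovery analysis should find.
#'
#' @param length_mm Gut length (mm).
#' @param duration_min Recording duration (min).
#' @param dx_mm Axial resolution (mm per row).
#' @param dt_s Temporal resolution (s per column).
#' @param baseline_mm Resting diameter (mm).
#' @param rate_per_min Contraction initiation rate (events/min); the default
#'   matches the regular proximal-colon CMMC frequency of 0.38 per min.
#' @param speed_mm_s Aboral propagation speed (mm/s).
#' @param depth Fractional diameter decrease inside a band, in (0, 1).
#' @param band_mm Longitudinal width of the contracted band (mm).
#' @param jitter_frac Onset jitter as a fraction of the inter-event spacing.
#' @param noise_sd_mm Additive Gaussian noise on the map (mm).
#' @return A `sim_motility_config` list.
#' @export
sim_motility_config <- function(length_mm = 60,
                                duration_min = 15,
                                dx_mm = 0.5,
                                dt_s = 1,
                                baseline_mm = 3,
                                rate_per_min = 0.38,
                                speed_mm_s = 2,
                                depth = 0.4,
                                band_mm = 10,
                                jitter_frac = 0.2,
                                noise_sd_mm = 0) {
  cfg <- as.list(environment())
  if (depth <= 0 || depth >= 1) stop("depth must be in (0, 1)")
  if (rate_per_min < 0) stop("rate_per_min must be >= 0")
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0")
  class(cfg) <- "sim_motility_config"
  cfg
}

#' Generate a synthetic diameter map with propagating contraction bands
#'
#' @param config A [sim_motility_config()].
#' @param seed Integer seed (controls onset jitter and noise).
#' @return List with `map` (a [diameter_map()]) and `truth` (onset times,
#'   configured rate, speed, depth and event count).
#' @export
generate_motility_map <- function(config = sim_motility_config(), seed = 1) {
  stopifnot(inherits(config, "sim_motility_config"))
  set.seed(seed)
  p <- as.integer(ceiling(config$length_mm / config$dx_mm))
  duration_s <- config$duration_min * 60
  tn <- as.integer(ceiling(duration_s / config$dt_s))
  D <- matrix(config$baseline_mm, p, tn)

  n_events <- round(config$rate_per_min * config$duration_min)
  onsets <- numeric(0)
  if (n_events > 0) {
    spacing <- duration_s / n_events
    onsets <- (seq_len(n_events) - 0.5) * spacing +
      stats::runif(n_events, -0.5, 0.5) * config$jitter_frac * spacing
    onsets <- pmin(pmax(onsets, 0), duration_s - config$dt_s)
    pos_mm <- (seq_len(p) - 1) * config$dx_mm
    contracted <- config$baseline_mm * (1 - config$depth)
    for (t0 in onsets) {
      t_end <- t0 + (config$length_mm + config$band_mm) / config$speed_mm_s
      cols <- which((seq_len(tn) - 1) * config$dt_s >= t0 &
                    (seq_len(tn) - 1) * config$dt_s <= t_end)
      for (cc in cols) {
        center <- config$speed_mm_s * ((cc - 1) * config$dt_s - t0)
        rows <- abs(pos_mm - center) <= config$band_mm / 2
        D[rows, cc] <- pmin(D[rows, cc], contracted)
      }
    }
  }
  if (config$noise_sd_mm > 0) {
    D <- pmax(D + stats::rnorm(length(D), 0, config$noise_sd_mm), 0)
  }
  list(
    map = diameter_map(D, config$dx_mm, config$dt_s),
    truth = list(onset_s = onsets, n_events = n_events,
                 rate_per_min = config$rate_per_min,
                 speed_mm_s = config$speed_mm_s, depth = config$depth,
                 seed = seed)
  )
}
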
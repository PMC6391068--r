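# Shared in-code fixtures for the test suite.

# A small field keeps unit-test movies cheap; the acceptance tests use the
# full default field.
tiny_movie_config <- function(...) {
  defaults <- list(
    field_um = c(600, 400),
    n_ganglia = 4,
    neurons_per_ganglion = 2,
    gap_s = 20,
    tail_frames = 25
  )
  do.call(sim_movie_config, utils::modifyList(defaults, list(...)))
}

# Minimal hand-built movie: constant-intensity frames, one or two epochs.
flat_movie <- function(value = 100, hw = c(8, 8), tn = 12, n_epochs = 1,
                       pixel_size_um = 10) {
  frames <- array(value, dim = c(hw, tn))
  starts <- if (n_epochs == 2) c(5L, 9L) else 5L
  epochs <- tibble::tibble(start_frame = starts, end_frame = starts + 1L)
  recording_movie(frames, frame_rate_hz = 2, pixel_size_um = pixel_size_um,
                  stim_epochs = epochs, electrode_xy = c(40, 40),
                  oral_axis = c(-1, 0))
}

# One circular ROI covering pixels around a center (um).
disc_roi <- function(id = 1, cx = 40, cy = 40, diam = 25) {
  tibble::tibble(id = id, cx_um = cx, cy_um = cy, long_um = diam, short_um = diam)
}
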
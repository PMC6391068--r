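#' Default analysis configuration
#'
#' Bundles the analysis constants used across the pipeline: the baseline and
#' response windows for transient amplitudes, the responder criterion, the
#' amplitude-ratio class bounds, the electrode band width, the large-soma
#' cutoff, the contraction-detection depth, and the voxel contact distance.
#'
#' Defaults follow the conventions of the fingerprinting analysis: amplitude
#' ratios are binned by 0.2, the oral-aboral electrode band is 500 um wide in
#' total, large somas are those strictly above 200 um^2, and the ratio bounds
#' separating "reduced" / "unchanged" / "increased" responses are 0.8 and 1.2.
#'
#' @param baseline_frames Number of frames in each baseline window (frames).
#' @param response_window_s Length of the post-stimulus response window (s).
#' @param responder_k Noise multiplier of the responder threshold (unitless).
#' @param responder_floor Minimum dF/F0 amplitude counted as a response.
#' @param ratio_low,ratio_high Amplitude-ratio bounds between the reduced,
#'   unchanged and increased classes (unitless, `ratio_low < ratio_high`).
#' @param hist_bin_width Ratio histogram bin width (unitless).
#' @param hist_cap Ratios at or above this value are pooled in the top bin.
#' @param band_width_um Total width of the oral-aboral electrode band (um).
#' @param large_soma_cutoff_um2 Strict lower cutoff for "large" somas (um^2).
#' @param contraction_depth Fractional diameter decrease below the per-position
#'   baseline that counts as a contraction (fraction of baseline, in (0,1)).
#' @param min_extent_mm Minimum longitudinal span of a motility event (mm).
#' @param contact_distance_vox Chebyshev distance (voxels) defining surface
#'   contact in 3D mask quantification.
#' @param rng_seed Integer seed used by simulation helpers.
#'
#' @return A `run_config` object (named list).
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$band_width_um
run_config <- function(baseline_frames = 10L,
                       response_window_s = 10,
                       responder_k = 5,
                       responder_floor = 0.05,
                       ratio_low = 0.8,
                       ratio_high = 1.2,
                       hist_bin_width = 0.2,
                       hist_cap = 2.4,
                       band_width_um = 500,
                       large_soma_cutoff_um2 = 200,
                       contraction_depth = 0.3,
                       min_extent_mm = 5,
                       contact_distance_vox = 1L,
                       rng_seed = 1L) {
  cfg <- list(
    baseline_frames = as.integer(baseline_frames),
    response_window_s = as.numeric(response_window_s),
    responder_k = as.numeric(responder_k),
    responder_floor = as.numeric(responder_floor),
    ratio_low = as.numeric(ratio_low),
    ratio_high = as.numeric(ratio_high),
    hist_bin_width = as.numeric(hist_bin_width),
    hist_cap = as.numeric(hist_cap),
    band_width_um = as.numeric(band_width_um),
    large_soma_cutoff_um2 = as.numeric(large_soma_cutoff_um2),
    contraction_depth = as.numeric(contraction_depth),
    min_extent_mm = as.numeric(min_extent_mm),
    contact_distance_vox = as.integer(contact_distance_vox),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop("all run_config fields must be numeric")
  bad <- names(cfg)[vapply(cfg, function(x) length(x) != 1 || !is.finite(x) || x <= 0, logical(1))]
  if (length(bad)) stop("run_config fields must be single positive numbers: ", paste(bad, collapse = ", "))
  if (cfg$ratio_low >= cfg$ratio_high) stop("ratio_low must be < ratio_high")
  if (cfg$contraction_depth >= 1) stop("contraction_depth must be in (0, 1)")
  invisible(cfg)
}

#' Read or write a run configuration file
#'
#' The format is chosen by file extension: `.yaml`/`.yml` or `.json`. Keys not
#' belonging to `run_config()` are an error, so typos cannot silently fall back
#' to defaults. The round trip is lossless.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param cfg A `run_config` object.
#' @return `read_config()` returns a `run_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- switch(config_format(path),
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE)
  )
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  switch(config_format(path),
    yaml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  )
  invisible(path)
}

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  stop("config format not recognized (use .yaml/.yml/.json): ", path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
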
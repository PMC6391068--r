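#' Configuration of the synthetic projection-tracing generator
#'
#' Emulates sparse-labelling axon tracing in the proximal and distal colon:
#' per-region sample sizes (defaults 57 proximal, 61 distal, matching typical
#' labelling yields), a traceable fraction (axons whose full length could be
#' followed), orientation proportions among traced axons, and a two-component
#' Gaussian length mixture (short vs long projections) truncated at zero.
#'
#' @param n_per_region Named counts `c(proximal=, distal=)`.
#' @param traceable_frac Named fraction of fully traceable axons per region.
#' @param orient_props Named list (per region) of proportions over
#'   `oral`, `aboral`, `circumferential` among traced axons.
#' @param mix_means,mix_sds,mix_weights Two-component Gaussian length mixture
#'   (mm); weights must sum to 1, sds must be positive.
#' @return A `sim_projection_config` list.
#' @export
sim_projection_config <- function(n_per_region = c(proximal = 57, distal = 61),
                                  traceable_frac = c(proximal = 37 / 57,
                                                     distal = 28 / 61),
                                  orient_props = list(
                                    proximal = c(oral = 14, aboral = 17,
                                                 circumferential = 6) / 37,
                                    distal = c(oral = 3, aboral = 24,
                                               circumferential = 1) / 28
                                  ),
                                  mix_means = c(1.8, 4.8),
                                  mix_sds = c(0.6, 1.0),
                                  mix_weights = c(0.55, 0.45)) {
  cfg <- as.list(environment())
  if (any(mix_sds <= 0)) stop("mixture sds must be > 0")
  if (abs(sum(mix_weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  class(cfg) <- "sim_projection_config"
  cfg
}

#' Draw from a two-component Gaussian mixture truncated at zero
#'
#' @param n Number of draws.
#' @param means,sds,weights Component parameters.
#' @return Positive numeric vector of length `n`.
#' @export
rmix_lengths <- function(n, means, sds, weights) {
  comp <- sample.int(2, n, replace = TRUE, prob = weights)
  x <- stats::rnorm(n, means[comp], sds[comp])
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), means[comp[bad]], sds[comp[bad]])
    bad <- which(x <= 0)
  }
  x
}

#' Generate synthetic traced projection neurons with ground truth
#'
#' @param config A [sim_projection_config()].
#' @param seed Integer seed.
#' @return List with `neurons` (tibble: `id`, `region`, `orientation`,
#'   `length_mm`, NA length when untraceable) and `truth` (mixture
#'   parameters, per-region orientation counts, seed).
#' @export
generate_projections <- function(config = sim_projection_config(), seed = 1) {
  stopifnot(inherits(config, "sim_projection_config"))
  set.seed(seed)
  out <- list()
  for (region in names(config$n_per_region)) {
    n <- config$n_per_region[[region]]
    n_traced <- round(config$traceable_frac[[region]] * n)
    orient <- sample(names(config$orient_props[[region]]), n_traced,
                     replace = TRUE, prob = config$orient_props[[region]])
    len <- rmix_lengths(n_traced, config$mix_means, config$mix_sds,
                        config$mix_weights)
    out[[region]] <- tibble::tibble(
      region = region,
      orientation = c(orient, rep("untraceable", n - n_traced)),
      length_mm = c(len, rep(NA_real_, n - n_traced))
    )
  }
  neurons <- dplyr::bind_rows(out)
  neurons$id <- seq_len(nrow(neurons))
  neurons <- neurons[, c("id", "region", "orientation", "length_mm")]
  list(
    neurons = neurons,
    truth = list(mix_means = config$mix_means, mix_sds = config$mix_sds,
                 mix_weights = config$mix_weights,
                 n_per_region = config$n_per_region, seed = seed)
  )
}
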
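#' Regional wiring counts for the mouse large intestine
#'
#' Reference counts for the proximal vs distal colonic myenteric plexus:
#' neuron density per mm^2 (Hu+), fibers per interganglionic tract (Tuj1+),
#' responding neurons per 2.2 mm^2 field of view under focal tract
#' stimulation. These manually counted quantities enter the wiring model only
#' as numbers; supply your own to analyze other preparations.
#'
#' @param neurons_per_mm2 Named numeric `c(proximal=, distal=)`.
#' @param fibers_per_tract Named numeric `c(proximal=, distal=)`.
#' @param responders_per_fov Named numeric `c(proximal=, distal=)`.
#' @param fov_area_mm2 Imaged field area (mm^2).
#' @return A `wiring_counts` object.
#' @export
#' @examples
#' colon_wiring_counts()
colon_wiring_counts <- function(neurons_per_mm2 = c(proximal = 698.3, distal = 591.3),
                                fibers_per_tract = c(proximal = 35.9, distal = 18.2),
                                responders_per_fov = c(proximal = 123.5, distal = 41.0),
                                fov_area_mm2 = 2.2) {
  for (v in list(neurons_per_mm2, fibers_per_tract, responders_per_fov)) {
    if (!all(c("proximal", "distal") %in% names(v))) {
      stop("counts must be named vectors with 'proximal' and 'distal'")
    }
    if (any(v < 0)) stop("counts must be >= 0")
  }
  structure(list(
    neurons_per_mm2 = neurons_per_mm2,
    fibers_per_tract = fibers_per_tract,
    responders_per_fov = responders_per_fov,
    fov_area_mm2 = fov_area_mm2
  ), class = "wiring_counts")
}

#' Distal-to-proximal ratio
#'
#' @param value_dis,value_prox Regional values; `value_prox` must be > 0.
#' @return The quotient `value_dis / value_prox`.
#' @export
regional_ratio <- function(value_dis, value_prox) {
  if (any(value_prox <= 0)) stop("proximal value must be > 0")
  value_dis / value_prox
}

#' Predicted responders under the monosynaptic wiring model
#'
#' In the simplest wiring model every stimulated fiber belongs to a
#' monoaxonal neuron contacting exactly one postsynaptic partner, so focal
#' tract stimulation activates two neurons per fiber - one antidromically and
#' one synaptically. The fanout is a parameter so the model doubles as a
#' hypothesis screen.
#'
#' @param n_fibers Number of stimulated fibers (>= 0).
#' @param fanout Neurons activated per fiber (default 2).
#' @return Predicted responder count.
#' @export
#' @examples
#' predict_responders(18)  # 36
predict_responders <- function(n_fibers, fanout = 2) {
  if (any(n_fibers < 0)) stop("n_fibers must be >= 0")
  fanout * n_fibers
}

#' Wiring consistency report
#'
#' Compares the observed regional responder ratio with the ratio expected
#' from neuron density and fiber counts, and the observed responder numbers
#' with the monosynaptic prediction. Two reporting modes: `raw` divides the
#' raw regional means; `paper` mirrors conventional rounded reporting (the
#' neuron-density ratio rounded to 2 decimals, fiber counts rounded to whole
#' fibers before dividing), which is how 35.9/18.2 fibers become the familiar
#' 36/18 and a 0.50 ratio.
#'
#' @param counts A [colon_wiring_counts()] object.
#' @param fanout Model fanout (default 2).
#' @return List with `raw` and `paper` expected responder ratios, the
#'   `observed` responder ratio, per-region predicted vs observed responders
#'   and the excess factor observed/predicted.
#' @export
consistency_report <- function(counts, fanout = 2) {
  stopifnot(inherits(counts, "wiring_counts"))
  n <- counts$neurons_per_mm2
  f <- counts$fibers_per_tract
  r <- counts$responders_per_fov
  n_ratio_raw <- regional_ratio(n[["distal"]], n[["proximal"]])
  f_ratio_raw <- regional_ratio(f[["distal"]], f[["proximal"]])
  n_ratio_paper <- round(n_ratio_raw, 2)
  f_ratio_paper <- regional_ratio(round(f[["distal"]]), round(f[["proximal"]]))
  observed <- regional_ratio(r[["distal"]], r[["proximal"]])
  predicted <- predict_responders(round(f), fanout)
  res <- list(
    n_ratio = c(raw = n_ratio_raw, paper = n_ratio_paper),
    f_ratio = c(raw = f_ratio_raw, paper = f_ratio_paper),
    expected_r_ratio = c(raw = n_ratio_raw * f_ratio_raw,
                         paper = n_ratio_paper * f_ratio_paper),
    observed_r_ratio = observed,
    predicted_responders = predicted,
    observed_responders = r,
    excess_factor = r / predicted,
    fanout = fanout
  )
  class(res) <- "wiring_report"
  res
}

#' @export
print.wiring_report <- function(x, ...) {
  pct <- function(v) sprintf("%.3g%%", 100 * v)
  cat("<wiring_report>\n")
  cat(sprintf("  neuron ratio dis/prox : raw %.3f, reported %.2f\n",
              x$n_ratio["raw"], x$n_ratio["paper"]))
  cat(sprintf("  fiber ratio dis/prox  : raw %.3f, reported %.2f\n",
              x$f_ratio["raw"], x$f_ratio["paper"]))
  cat(sprintf("  expected responder ratio: raw %s, reported %s\n",
              pct(x$expected_r_ratio["raw"]), pct(x$expected_r_ratio["paper"])))
  cat(sprintf("  observed responder ratio: %s\n", pct(x$observed_r_ratio)))
  cat(sprintf("  model (fanout %g): predicted prox %g / dis %g, observed %g / %g\n",
              x$fanout, x$predicted_responders[["proximal"]],
              x$predicted_responders[["distal"]],
              x$observed_responders[["proximal"]],
              x$observed_responders[["distal"]]))
  cat(sprintf("  excess observed/predicted: prox %.2f, dis %.2f\n",
              x$excess_factor[["proximal"]], x$excess_factor[["distal"]]))
  invisible(x)
}
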
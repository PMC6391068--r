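#' Activity-over-time (AoT) image
#'
#' Builds the per-pixel amplitude image for one stimulation epoch: every pixel
#' inside a responding ROI carries that ROI's dF/F0 amplitude, all other
#' pixels are zero. Where responding ROIs overlap, the larger amplitude wins
#' (a display convention; the analysis never reads AoT pixels back).
#'
#' @param movie A [recording_movie()].
#' @param rois ROI table (see [compute_responses()]).
#' @param responses Output of [compute_responses()].
#' @param epoch Stimulation epoch index.
#' @return `H x W` numeric matrix in dF/F0 units.
#' @export
build_aot <- function(movie, rois, responses, epoch) {
  if (!epoch %in% responses$stim_index) stop("epoch index out of range: ", epoch)
  d <- dim(movie$frames)
  img <- matrix(0, d[1], d[2])
  resp <- responses[responses$stim_index == epoch & responses$responded, ]
  rois <- tibble::as_tibble(rois)
  for (i in seq_len(nrow(resp))) {
    roi <- rois[rois$id == resp$roi_id[i], ]
    px <- roi_pixels(roi, d[1:2], movie$pixel_size_um)
    idx <- cbind(px[, "row"], px[, "col"])
    img[idx] <- pmax(img[idx], resp$amplitude[i])
  }
  img
}

#' Amplitude ratio between two consecutive stimulations
#'
#' `ratio = amp_es2 / amp_es1`, defined only for neurons that responded to
#' both stimuli. A non-positive first amplitude together with a responder flag
#' is inconsistent input and raises an error.
#'
#' @param amp_es1,amp_es2 dF/F0 amplitudes of the first and second response.
#' @return The unitless ratio.
#' @export
amplitude_ratio <- function(amp_es1, amp_es2) {
  if (any(amp_es1 <= 0)) stop("amp_es1 must be > 0 for a responding neuron")
  amp_es2 / amp_es1
}

#' Five-class response signature
#'
#' Classifies a neuron by its responses to two consecutive stimulations:
#' * Type I  ("blocked"): responded to ES1 only;
#' * Type II ("reduced"): both, ratio < `low`;
#' * Type III ("unchanged"): both, `low` <= ratio <= `high`;
#' * Type IV ("increased"): both, ratio > `high`;
#' * Type V  ("new"): responded to ES2 only.
#'
#' Boundary ratios are assigned to Type III (the "unchanged" interval is
#' closed). Neurons that responded to neither stimulus must be excluded
#' before classification and raise an error here.
#'
#' @param responded_es1,responded_es2 Logical responder flags.
#' @param ratio Amplitude ratio; required iff both responded.
#' @param low,high Class bounds (defaults 0.8 and 1.2).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @export
classify_signature <- function(responded_es1, responded_es2, ratio = NA_real_,
                               low = 0.8, high = 1.2) {
  if (!responded_es1 && !responded_es2) {
    stop("neuron responded to neither stimulus; exclude before classification")
  }
  if (responded_es1 && !responded_es2) return("I")
  if (!responded_es1 && responded_es2) return("V")
  if (is.na(ratio)) stop("ratio required when the neuron responded to both stimuli")
  if (ratio < low) "II" else if (ratio <= high) "III" else "IV"
}

#' Signature records for a stimulation pair
#'
#' Joins the per-epoch responses of a movie into one record per responding
#' neuron: both amplitudes, the amplitude ratio (NA for Types I and V) and the
#' five-class signature. Neurons responding to neither stimulus are dropped.
#'
#' @param responses Output of [compute_responses()] for a two-epoch movie.
#' @param condition_pair Label of the stimulation pair (e.g. `"Ctrl-Ctrl"`).
#' @param prep_id Preparation identifier carried into summaries.
#' @param config A [run_config()] supplying the ratio class bounds.
#' @return Tibble: `roi_id`, `amp_es1`, `amp_es2`, `ratio`, `cls`,
#'   `condition_pair`, `prep_id`.
#' @export
signature_records <- function(responses, condition_pair = "Ctrl-Ctrl",
                              prep_id = 1L, config = run_config()) {
  e1 <- responses[responses$stim_index == 1, ]
  e2 <- responses[responses$stim_index == 2, ]
  if (nrow(e1) == 0 || nrow(e2) == 0) stop("responses must cover two stimulation epochs")
  j <- dplyr::inner_join(e1, e2, by = "roi_id", suffix = c("_es1", "_es2"))
  j <- j[j$responded_es1 | j$responded_es2, ]
  cls <- character(nrow(j))
  ratio <- rep(NA_real_, nrow(j))
  for (i in seq_len(nrow(j))) {
    if (j$responded_es1[i] && j$responded_es2[i]) {
      ratio[i] <- amplitude_ratio(j$amplitude_es1[i], j$amplitude_es2[i])
    }
    cls[i] <- classify_signature(j$responded_es1[i], j$responded_es2[i],
                                 ratio[i], config$ratio_low, config$ratio_high)
  }
  tibble::tibble(
    roi_id = j$roi_id,
    amp_es1 = j$amplitude_es1,
    amp_es2 = j$amplitude_es2,
    ratio = ratio,
    cls = factor(cls, levels = c("I", "II", "III", "IV", "V")),
    condition_pair = condition_pair,
    prep_id = prep_id
  )
}

#' Amplitude-ratio histogram with categorical blocked/new bins
#'
#' Ratios are binned in half-open `[e, e + width)` bins starting at 0; ratios
#' at or above `cap` are pooled in a single top bin. Type I ("blocked") and
#' Type V ("new") neurons, whose ratio is undefined, occupy two categorical
#' bins. Percentages are over all records and sum to 100.
#'
#' @param records Output of [signature_records()].
#' @param width Bin width (default 0.2).
#' @param cap Pooling cap for large ratios (default 2.4).
#' @return Tibble: `bin` (label), `lower`, `upper` (NA for categorical bins),
#'   `n`, `pct`.
#' @export
ratio_histogram <- function(records, width = 0.2, cap = 2.4) {
  if (nrow(records) == 0) stop("no signature records to bin")
  edges <- seq(0, cap, by = width)
  labs <- c(sprintf("[%.1f,%.1f)", edges[-length(edges)], edges[-1]),
            sprintf("%.1f+", cap))
  n_num <- integer(length(labs))
  r <- records$ratio[!is.na(records$ratio)]
  idx <- pmin(findInterval(r, edges), length(labs))
  for (k in idx) n_num[k] <- n_num[k] + 1L
  lower <- c(edges[-length(edges)], cap)
  upper <- c(edges[-1], Inf)
  out <- tibble::tibble(
    bin = c("blocked", labs, "new"),
    lower = c(NA, lower, NA),
    upper = c(NA, upper, NA),
    n = c(sum(records$cls == "I"), n_num, sum(records$cls == "V"))
  )
  out$pct <- 100 * out$n / nrow(records)
  stopifnot(abs(sum(out$pct) - 100) < 1e-9)
  out
}

#' Class percentages across preparations
#'
#' Computes per-preparation class fractions and then their mean and SEM across
#' preparations, separately per condition pair. A preparation contributing no
#' responders is an error.
#'
#' @param records Output of [signature_records()], possibly concatenated over
#'   preparations.
#' @return Tibble: `condition_pair`, `cls`, `n_preps`, `mean_pct`, `sem_pct`.
#' @export
summarize_classes <- function(records) {
  if (nrow(records) == 0) stop("no records")
  groups <- split(records, interaction(records$condition_pair, records$prep_id,
                                       drop = TRUE))
  per_prep <- dplyr::bind_rows(lapply(groups, function(g) {
    if (nrow(g) == 0) stop("a preparation has zero responders")
    tab <- table(g$cls)  # factor: all five levels present
    tibble::tibble(
      condition_pair = g$condition_pair[1],
      prep_id = g$prep_id[1],
      cls = factor(names(tab), levels = levels(g$cls)),
      pct = 100 * as.numeric(tab) / nrow(g)
    )
  }))
  per_prep |>
    dplyr::group_by(.data$condition_pair, .data$cls) |>
    dplyr::summarise(
      n_preps = dplyr::n(),
      mean_pct = mean(.data$pct),
      sem_pct = stats::sd(.data$pct) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' End-to-end fingerprint pipeline for one movie
#'
#' Convenience wrapper: responses, signature records and the ratio histogram
#' in one call.
#'
#' @inheritParams compute_responses
#' @inheritParams signature_records
#' @return List with `responses`, `signatures`, `histogram`.
#' @export
fingerprint_pipeline <- function(movie, rois, config = run_config(),
                                 condition_pair = "Ctrl-Ctrl", prep_id = 1L) {
  responses <- compute_responses(movie, rois, config)
  signatures <- signature_records(responses, condition_pair, prep_id, config)
  list(
    responses = responses,
    signatures = signatures,
    histogram = ratio_histogram(signatures, config$hist_bin_width, config$hist_cap)
  )
}

#' Agreement between pipeline classes and generator ground truth
#'
#' Joins signature records to the ground-truth ROI table by `roi_id`. Neurons
#' present in the truth but dropped by the pipeline (detected in neither
#' epoch) count as disagreements.
#'
#' @param truth A `ground_truth` from [generate_layout()]/[generate_movie()].
#' @param signatures Output of [signature_records()].
#' @return Fraction of ground-truth neurons assigned their true class.
#' @export
class_accuracy <- function(truth, signatures) {
  tr <- truth$rois
  m <- match(tr$id, signatures$roi_id)
  called <- as.character(signatures$cls[m])
  mean(!is.na(called) & called == as.character(tr$cls))
}
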
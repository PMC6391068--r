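#' Soma area from ROI axes
#'
#' The soma surface is taken as the ellipse with the ROI's own extents: the
#' axes are full diameters, so `area = pi * long/2 * short/2`.
#'
#' @param long_axis,short_axis Full axis lengths (um), `long >= short > 0`.
#' @return Area (um^2). Vectorized.
#' @export
#' @examples
#' ellipse_area(10, 10)  # ~78.54 um^2
ellipse_area <- function(long_axis, short_axis) {
  if (any(short_axis <= 0)) stop("axes must be positive")
  if (any(long_axis < short_axis)) stop("long_axis must be >= short_axis")
  pi * (long_axis / 2) * (short_axis / 2)
}

#' Soma-size summary by group, with the large-cell filter
#'
#' Per-group mean, SEM and count of soma areas, plus the number of "large"
#' cells. "Large" is strictly greater than the cutoff (a cell of exactly
#' 200 um^2 is not large at the default cutoff). An empty group yields `n = 0`
#' rather than an error.
#'
#' @param records Data frame with a `soma_area_um2` column.
#' @param group_by Character vector of grouping columns (e.g. `"cls"`,
#'   `"condition_pair"`, `"region"`).
#' @param large_cutoff_um2 Strict cutoff for large somas (um^2, default 200).
#' @return Tibble with the grouping columns plus `n`, `mean_um2`, `sem_um2`,
#'   `n_large`.
#' @export
size_summary <- function(records, group_by = "cls", large_cutoff_um2 = 200) {
  records <- tibble::as_tibble(records)
  if (!"soma_area_um2" %in% names(records)) stop("records need a soma_area_um2 column")
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by)), .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_um2 = if (dplyr::n() > 0) mean(.data$soma_area_um2) else NA_real_,
      sem_um2 = if (dplyr::n() > 1) {
        stats::sd(.data$soma_area_um2) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n_large = sum(.data$soma_area_um2 > large_cutoff_um2),
      .groups = "drop"
    )
}

#' Flag large somas
#'
#' @inheritParams size_summary
#' @return `records` with an added logical `large` column
#'   (strictly above the cutoff).
#' @export
flag_large <- function(records, large_cutoff_um2 = 200) {
  records <- tibble::as_tibble(records)
  records$large <- records$soma_area_um2 > large_cutoff_um2
  records
}
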
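#' Express ROI centers in the electrode frame
#'
#' Rotates/translates ROI centers into a frame anchored at the stimulation
#' electrode, with the axial coordinate along the gut axis (aboral positive)
#' and the circumferential coordinate perpendicular to it. The transform is
#' rigid, so pairwise distances are preserved.
#'
#' @param centers Data frame with `cx_um`, `cy_um` (and typically `roi_id`,
#'   `cls`, `soma_area_um2`, which are carried through).
#' @param electrode_xy Electrode position (um, length 2).
#' @param oral_axis Unit vector pointing orally (length 2).
#' @return Tibble with added columns `rel_axial_um` (aboral > 0) and
#'   `rel_circ_um`.
#' @export
to_electrode_frame <- function(centers, electrode_xy, oral_axis) {
  if (length(oral_axis) != 2 || sum(oral_axis^2) == 0) {
    stop("oral_axis must be a non-zero 2-vector")
  }
  u <- oral_axis / sqrt(sum(oral_axis^2))
  aboral <- -u                      # aboral is the positive axial direction
  perp <- c(-aboral[2], aboral[1])  # right-handed perpendicular
  centers <- tibble::as_tibble(centers)
  dx <- centers$cx_um - electrode_xy[1]
  dy <- centers$cy_um - electrode_xy[2]
  centers$rel_axial_um <- dx * aboral[1] + dy * aboral[2]
  centers$rel_circ_um <- dx * perp[1] + dy * perp[2]
  centers
}

filter_cls <- function(records, cls_filter) {
  if (!is.null(cls_filter)) records <- records[records$cls %in% cls_filter, ]
  if (nrow(records) == 0) stop("no records left after class filter")
  records
}

#' Fraction of neurons located aboral to the electrode
#'
#' Records exactly on the electrode's transverse line (`rel_axial_um == 0`)
#' count as aboral (half-open convention).
#'
#' @param records Output of [to_electrode_frame()], with a `cls` column when
#'   `cls_filter` is used.
#' @param cls_filter Optional character vector of classes to keep.
#' @return Fraction in `[0, 1]`.
#' @export
aboral_fraction <- function(records, cls_filter = NULL) {
  records <- filter_cls(records, cls_filter)
  mean(records$rel_axial_um >= 0)
}

#' Fraction of neurons in the oral-aboral electrode band
#'
#' The band is centered on the electrode with *total* axial width
#' `band_width_um` (i.e. within `band_width_um / 2` on either side), boundary
#' inclusive.
#'
#' @inheritParams aboral_fraction
#' @param band_width_um Total band width (um, default 500).
#' @return Fraction in `[0, 1]`.
#' @export
band_fraction <- function(records, cls_filter = NULL, band_width_um = 500) {
  if (band_width_um <= 0) stop("band_width_um must be > 0")
  records <- filter_cls(records, cls_filter)
  mean(abs(records$rel_axial_um) <= band_width_um / 2)
}

#' Spatial records for classified responders
#'
#' Joins signature records to ROI geometry and expresses each responder's
#' position in the electrode frame, yielding the table behind class-specific
#' spatial analyses (dotplots, aboral fractions, electrode-band occupancy).
#'
#' @param rois ROI table with `id`, `cx_um`, `cy_um` and (optionally)
#'   `long_um`, `short_um`.
#' @param signatures Output of [signature_records()].
#' @param electrode_xy Electrode position (um).
#' @param oral_axis Unit vector pointing orally.
#' @return Tibble: `roi_id`, `rel_axial_um`, `rel_circ_um`, `cls`,
#'   `soma_area_um2` (when axes are available).
#' @export
spatial_records <- function(rois, signatures, electrode_xy, oral_axis) {
  rois <- tibble::as_tibble(rois)
  m <- match(signatures$roi_id, rois$id)
  if (anyNA(m)) stop("signatures contain roi_ids absent from the ROI table")
  rec <- tibble::tibble(
    roi_id = signatures$roi_id,
    cx_um = rois$cx_um[m],
    cy_um = rois$cy_um[m],
    cls = signatures$cls
  )
  if (all(c("long_um", "short_um") %in% names(rois))) {
    rec$soma_area_um2 <- ellipse_area(rois$long_um[m], rois$short_um[m])
  }
  rec <- to_electrode_frame(rec, electrode_xy, oral_axis)
  rec[, c("roi_id", "rel_axial_um", "rel_circ_um", "cls",
          intersect("soma_area_um2", names(rec)))]
}
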
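#' Paired 3D masks for contact quantification
#'
#' @param soma_mask,varicosity_mask Logical (or 0/1) 3D arrays of identical
#'   shape.
#' @param voxel_size_um Voxel size per axis (um, length 1 or 3).
#' @param soma_labels Optional integer 3D array labelling individual somas
#'   (0 = background); enables per-neuron averaging.
#' @return A `contact_volume` object.
#' @export
contact_volume <- function(soma_mask, varicosity_mask, voxel_size_um = 1,
                           soma_labels = NULL) {
  if (length(dim(soma_mask)) != 3 || length(dim(varicosity_mask)) != 3) {
    stop("masks must be 3D arrays")
  }
  if (!identical(dim(soma_mask), dim(varicosity_mask))) {
    stop("masks must have the same shape")
  }
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be > 0")
  if (!is.null(soma_labels) && !identical(dim(soma_labels), dim(soma_mask))) {
    stop("soma_labels must match the mask shape")
  }
  structure(list(
    soma_mask = soma_mask != 0,
    varicosity_mask = varicosity_mask != 0,
    voxel_size_um = rep(as.numeric(voxel_size_um), length.out = 3),
    soma_labels = soma_labels
  ), class = "contact_volume")
}

shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]; okz <- fz >= 1 & fz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[fx[okx], fy[oky], fz[okz]]
  out
}

#' Surface voxels of a 3D binary mask
#'
#' A mask voxel is a surface voxel when at least one of its six face-adjacent
#' neighbors is background or lies outside the volume.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @return Logical 3D array marking surface voxels.
#' @export
surface_voxels <- function(mask) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array")
  if (!all(mask %in% c(0, 1, TRUE, FALSE))) stop("mask must be binary")
  m <- mask != 0
  interior <- m
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    interior <- interior & shift3(m, s[1], s[2], s[3], fill = FALSE)
  }
  m & !interior
}

dilate_chebyshev <- function(m, distance) {
  out <- m
  for (i in seq_len(distance)) {
    acc <- out
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      acc <- acc | shift3(out, dx, dy, dz, fill = FALSE)
    }
    out <- acc
  }
  out
}

#' Surface-to-surface contact fraction
#'
#' Quantifies the proportion of the soma surface in contact with
#' varicosities: a soma surface voxel is a contact voxel when a varicosity
#' voxel lies within `distance_vox` (Chebyshev distance, so the default 1
#' means the 26-neighborhood). The fraction is contact voxels over all soma
#' surface voxels; with a label image the per-neuron fractions and their mean
#' are also reported.
#'
#' @param volume A [contact_volume()].
#' @param distance_vox Chebyshev contact distance in voxels (>= 0, default 1).
#' @return A `contact_result` list: `surface_vox`, `contact_vox`, `fraction`,
#'   and (when labels are present) a `per_neuron` tibble plus
#'   `mean_neuron_fraction`.
#' @export
contact_fraction <- function(volume, distance_vox = 1) {
  stopifnot(inherits(volume, "contact_volume"))
  if (distance_vox < 0) stop("distance_vox must be >= 0")
  if (!any(volume$soma_mask)) stop("soma mask is empty")
  surf <- surface_voxels(volume$soma_mask)
  near <- if (distance_vox == 0) {
    volume$varicosity_mask
  } else {
    dilate_chebyshev(volume$varicosity_mask, as.integer(distance_vox))
  }
  contact <- surf & near
  res <- list(
    surface_vox = sum(surf),
    contact_vox = sum(contact),
    fraction = sum(contact) / sum(surf)
  )
  if (!is.null(volume$soma_labels)) {
    labs <- sort(unique(volume$soma_labels[volume$soma_labels > 0]))
    per <- lapply(labs, function(l) {
      s <- surf & (volume$soma_labels == l)
      tibble::tibble(label = l, surface_vox = sum(s), contact_vox = sum(s & near),
                     fraction = sum(s & near) / max(sum(s), 1))
    })
    res$per_neuron <- dplyr::bind_rows(per)
    res$mean_neuron_fraction <- mean(res$per_neuron$fraction)
  }
  class(res) <- "contact_result"
  res
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("<contact_result> %d / %d surface voxels in contact (fraction %.3f)\n",
              x$contact_vox, x$surface_vox, x$fraction))
  if (!is.null(x$per_neuron)) {
    cat(sprintf("  %d neurons, mean per-neuron fraction %.3f\n",
                nrow(x$per_neuron), x$mean_neuron_fraction))
  }
  invisible(x)
}
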
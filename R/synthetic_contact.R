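#' Configuration of the synthetic contact-volume generator
#'
#' Builds a spherical soma phantom and tangent spherical varicosity phantoms
#' in a 3D voxel volume, aiming for a target fraction of the soma surface in
#' contact with varicosities.
#'
#' @param dim_vox Volume shape (3 integers).
#' @param voxel_size_um Isotropic voxel size (um).
#' @param soma_radius_vox Soma sphere radius (voxels).
#' @param vari_radius_vox Varicosity sphere radius (voxels).
#' @param target_coverage Target surface-contact fraction in `[0, 1]`
#'   (0 generates no varicosities).
#' @param max_varicosities Safety cap on placed varicosities.
#' @return A `sim_contact_config` list.
#' @export
sim_contact_config <- function(dim_vox = c(48, 48, 48),
                               voxel_size_um = 0.5,
                               soma_radius_vox = 10,
                               vari_radius_vox = 3,
                               target_coverage = 0.15,
                               max_varicosities = 60) {
  cfg <- as.list(environment())
  if (target_coverage < 0 || target_coverage > 1) {
    stop("target_coverage must be in [0, 1]")
  }
  center <- (dim_vox + 1) / 2
  if (any(center - soma_radius_vox < 1) || any(center + soma_radius_vox > dim_vox)) {
    stop("soma sphere does not fit inside the volume")
  }
  class(cfg) <- "sim_contact_config"
  cfg
}

sphere_mask <- function(dim_vox, center, radius) {
  x <- seq_len(dim_vox[1]); y <- seq_len(dim_vox[2]); z <- seq_len(dim_vox[3])
  dx2 <- (x - center[1])^2
  dy2 <- (y - center[2])^2
  dz2 <- (z - center[3])^2
  array(outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2, dim_vox)
}

#' Generate a synthetic soma/varicosity contact volume with ground truth
#'
#' Varicosity spheres are placed tangent to the soma sphere in random
#' directions (rejecting directions too close to an existing varicosity)
#' until the realized surface coverage reaches the target or the cap is hit.
#' Realized coverage is recorded in the ground truth as the fraction of soma
#' surface voxels whose center lies within `sqrt(3)` voxels (Euclidean) of a
#' varicosity voxel center, computed by nearest-neighbour distances - an
#' independent evaluation of the default 26-neighborhood contact criterion.
#' The two masks are disjoint.
#'
#' @param config A [sim_contact_config()].
#' @param seed Integer seed.
#' @return List with `volume` (a [contact_volume()]) and `truth`
#'   (`target_coverage`, `realized_coverage`, varicosity centers, seed).
#' @export
generate_contact_volume <- function(config = sim_contact_config(), seed = 1) {
  stopifnot(inherits(config, "sim_contact_config"))
  set.seed(seed)
  dims <- config$dim_vox
  center <- (dims + 1) / 2
  soma <- sphere_mask(dims, center, config$soma_radius_vox)
  surf_idx <- which(surface_voxels(soma), arr.ind = TRUE)

  vari <- array(FALSE, dims)
  centers <- matrix(numeric(0), 0, 3)
  if (config$target_coverage > 0) {
    rv <- config$vari_radius_vox
    min_sep <- 1.2 * rv
    tries <- 0
    while (nrow(centers) < config$max_varicosities && tries < 2000) {
      if (realized_coverage(surf_idx, vari & !soma) >= config$target_coverage) break
      tries <- tries + 1
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      vc <- center + u * (config$soma_radius_vox + rv)
      if (any(vc - rv < 1) || any(vc + rv > dims)) next
      if (nrow(centers) &&
          any(sqrt(rowSums(sweep(centers, 2, vc)^2)) < min_sep)) next
      centers <- rbind(centers, vc)
      vari <- vari | sphere_mask(dims, vc, rv)
    }
  }
  vari <- vari & !soma
  list(
    volume = contact_volume(soma, vari, config$voxel_size_um),
    truth = list(target_coverage = config$target_coverage,
                 realized_coverage = realized_coverage(surf_idx, vari),
                 n_varicosities = nrow(centers),
                 centers = centers, seed = seed)
  )
}

# Coverage by nearest-neighbour distances: a surface voxel is covered when
# its center lies within sqrt(3) of a varicosity voxel center, which on the
# integer grid is exactly Chebyshev distance 1 (the 26-neighborhood). Serves
# as an independent computation of the default contact criterion.
realized_coverage <- function(surf_idx, vari_mask) {
  vi <- which(vari_mask, arr.ind = TRUE)
  if (nrow(vi) == 0) return(0)
  covered <- vapply(seq_len(nrow(surf_idx)), function(i) {
    d2 <- (vi[, 1] - surf_idx[i, 1])^2 + (vi[, 2] - surf_idx[i, 2])^2 +
          (vi[, 3] - surf_idx[i, 3])^2
    min(d2) <= 3
  }, logical(1))
  mean(covered)
}
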
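test_that("surface voxels are mask voxels with a face-adjacent background", {
  one <- array(FALSE, dim = c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_identical(surface_voxels(one), one)

  cube <- array(FALSE, dim = c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  s <- surface_voxels(cube)
  expect_equal(sum(s), 26)          # 27 voxels minus 1 interior
  expect_false(s[3, 3, 3])

  empty <- array(FALSE, dim = c(4, 4, 4))
  expect_equal(sum(surface_voxels(empty)), 0)
  # voxels on the volume border are surface
  solid <- array(TRUE, dim = c(3, 3, 3))
  expect_equal(sum(surface_voxels(solid)), 26)
  expect_error(surface_voxels(array(2, dim = c(2, 2, 2))), "binary")
})

test_that("contact fraction spans its closed range on analytic phantoms", {
  dims <- c(9, 9, 9)
  cube <- array(FALSE, dims); cube[4:6, 4:6, 4:6] <- TRUE
  # enveloping shell one voxel away from every cube face
  shell <- array(FALSE, dims); shell[3:7, 3:7, 3:7] <- TRUE; shell[4:6, 4:6, 4:6] <- FALSE
  full <- contact_fraction(contact_volume(cube, shell))
  expect_equal(full$fraction, 1)
  expect_equal(full$surface_vox, 26)
  expect_equal(full$contact_vox, 26)

  none <- contact_fraction(contact_volume(cube, array(FALSE, dims)))
  expect_equal(none$fraction, 0)
  expect_error(contact_fraction(contact_volume(array(FALSE, dims), shell)), "empty")
})

test_that("a construction with half the surface in contact measures exactly 0.5", {
  dims <- c(9, 9, 9)
  soma <- array(FALSE, dims)
  soma[5, 5, 5:6] <- TRUE            # two voxels, both surface
  vari <- array(FALSE, dims)
  vari[5, 5, 4] <- TRUE              # adjacent to (5,5,5) only
  res <- contact_fraction(contact_volume(soma, vari))
  expect_equal(res$surface_vox, 2)
  expect_equal(res$fraction, 0.5)
})

test_that("contact is monotone in distance and translation invariant", {
  set.seed(51)
  dims <- c(16, 16, 16)
  soma <- array(FALSE, dims); soma[6:10, 6:10, 6:10] <- TRUE
  vari <- array(FALSE, dims)
  vari[cbind(sample(3:14, 12, TRUE), sample(3:14, 12, TRUE), sample(3:14, 12, TRUE))] <- TRUE
  vari <- vari & !soma
  vol <- contact_volume(soma, vari)
  fr <- vapply(0:3, function(d) contact_fraction(vol, d)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))

  sh <- function(a) {
    out <- array(FALSE, dims)
    out[2:16, 2:16, 2:16] <- a[1:15, 1:15, 1:15]
    out
  }
  moved <- contact_fraction(contact_volume(sh(soma), sh(vari)))
  expect_equal(moved$fraction, contact_fraction(vol)$fraction)
})

test_that("per-neuron averaging uses the soma label image", {
  dims <- c(12, 12, 6)
  soma <- array(FALSE, dims)
  labs <- array(0L, dims)
  soma[3, 3, 3] <- TRUE; labs[3, 3, 3] <- 1L
  soma[9, 9, 3] <- TRUE; labs[9, 9, 3] <- 2L
  vari <- array(FALSE, dims); vari[3, 4, 3] <- TRUE  # touches neuron 1 only
  res <- contact_fraction(contact_volume(soma, vari, soma_labels = labs))
  expect_equal(res$per_neuron$fraction, c(1, 0))
  expect_equal(res$mean_neuron_fraction, 0.5)
})

test_that("generated phantoms agree with their recorded realized coverage", {
  for (s in 1:3) {
    g <- generate_contact_volume(sim_contact_config(target_coverage = 0.2), seed = s)
    res <- contact_fraction(g$volume)
    expect_equal(res$fraction, g$truth$realized_coverage, tolerance = 1e-12)
    expect_false(any(g$volume$soma_mask & g$volume$varicosity_mask))
  }
  g0 <- generate_contact_volume(sim_contact_config(target_coverage = 0), seed = 1)
  expect_equal(contact_fraction(g0$volume)$fraction, 0)
  expect_error(sim_contact_config(soma_radius_vox = 40), "fit inside")
})
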
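test_that("electrode-frame coordinates follow the aboral-positive convention", {
  el <- c(500, 300)
  oral <- c(-1, 0)  # oral is -x, so aboral offsets are +x
  at <- function(x, y) tibble::tibble(cx_um = x, cy_um = y)
  r0 <- to_electrode_frame(at(500, 300), el, oral)
  expect_equal(r0$rel_axial_um, 0)
  expect_equal(r0$rel_circ_um, 0)

  r1 <- to_electrode_frame(at(600, 300), el, oral)
  expect_equal(r1$rel_axial_um, 100)
  expect_equal(r1$rel_circ_um, 0)

  expect_error(to_electrode_frame(at(0, 0), el, c(0, 0)), "non-zero")
})

test_that("the electrode-frame transform is a rigid isometry", {
  set.seed(31)
  pts <- tibble::tibble(cx_um = runif(20, 0, 1000), cy_um = runif(20, 0, 1000))
  for (ang in c(0.3, 1.2, 2.9)) {
    oral <- c(cos(ang), sin(ang))
    tr <- to_electrode_frame(pts, c(200, 700), oral)
    d_orig <- dist(cbind(pts$cx_um, pts$cy_um))
    d_new <- dist(cbind(tr$rel_axial_um, tr$rel_circ_um))
    expect_equal(as.numeric(d_new), as.numeric(d_orig), tolerance = 1e-9)
  }
})

test_that("aboral and band fractions follow their boundary conventions", {
  recs <- tibble::tibble(
    rel_axial_um = c(100, 250, 400, 0, 250, 300, -250, 50, 80, 90),
    rel_circ_um = 0,
    cls = factor(rep("I", 10), levels = c("I", "II", "III", "IV", "V"))
  )
  # 9 of 10 at rel_axial >= 0 (0 counts as aboral)
  expect_equal(aboral_fraction(recs, "I"), 0.9)
  all_oral <- tibble::tibble(rel_axial_um = c(-10, -5), cls = "I")
  expect_equal(aboral_fraction(all_oral), 0)
  # complement property
  expect_equal(aboral_fraction(recs) + mean(recs$rel_axial_um < 0), 1)

  expect_equal(band_fraction(tibble::tibble(rel_axial_um = c(0, 0, 0)), NULL), 1)
  expect_equal(band_fraction(tibble::tibble(rel_axial_um = 250), NULL), 1)   # inclusive
  expect_equal(band_fraction(tibble::tibble(rel_axial_um = 400), NULL), 0)
  expect_error(band_fraction(recs, "V"), "no records")
  expect_error(band_fraction(recs, "I", band_width_um = 0), "> 0")
})

test_that("fractions are invariant to joint translation of field and electrode", {
  set.seed(32)
  pts <- tibble::tibble(cx_um = runif(50, 0, 1000), cy_um = runif(50, 0, 1000))
  el <- c(500, 500)
  base <- to_electrode_frame(pts, el, c(-1, 0))
  shifted <- to_electrode_frame(
    dplyr::mutate(pts, cx_um = cx_um + 123, cy_um = cy_um - 77),
    el + c(123, -77), c(-1, 0))
  expect_equal(aboral_fraction(shifted), aboral_fraction(base))
  expect_equal(band_fraction(shifted), band_fraction(base))
})

test_that("generator spatial bias is recovered within binomial error", {
  cfg <- tiny_movie_config(n_ganglia = 10, neurons_per_ganglion = 10,
                           class_props = c(I = 1, II = 0, III = 0, IV = 0, V = 0),
                           p_aboral = c(I = 0.8, II = .5, III = .5, IV = .5, V = .5))
  truth <- generate_layout(cfg, seed = 9)
  rec <- to_electrode_frame(truth$rois, truth$electrode_xy, truth$oral_axis)
  p_hat <- aboral_fraction(rec, "I")
  expect_lt(abs(p_hat - 0.8), 1.96 * sqrt(0.8 * 0.2 / 100))
})

test_that("spatial records join signatures to geometry", {
  gm <- generate_movie(tiny_movie_config(), seed = 6)
  fp <- fingerprint_pipeline(gm$movie, gm$truth$rois)
  rec <- spatial_records(gm$truth$rois, fp$signatures,
                         gm$truth$electrode_xy, gm$truth$oral_axis)
  expect_equal(nrow(rec), nrow(fp$signatures))
  expect_true(all(c("rel_axial_um", "rel_circ_um", "cls", "soma_area_um2") %in% names(rec)))
})
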
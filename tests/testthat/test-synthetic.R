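test_that("generators are deterministic given the seed", {
  cfg <- tiny_movie_config()
  a <- generate_movie(cfg, seed = 12)
  b <- generate_movie(cfg, seed = 12)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_equal(a$truth$rois, b$truth$rois)
  c <- generate_movie(cfg, seed = 13)
  expect_false(identical(a$movie$frames, c$movie$frames))

  m1 <- generate_motility_map(seed = 3); m2 <- generate_motility_map(seed = 3)
  expect_identical(m1$map$D, m2$map$D)

  p1 <- generate_projections(seed = 3); p2 <- generate_projections(seed = 3)
  expect_equal(p1$neurons, p2$neurons)

  v1 <- generate_contact_volume(seed = 3); v2 <- generate_contact_volume(seed = 3)
  expect_identical(v1$volume$varicosity_mask, v2$volume$varicosity_mask)
})

test_that("movie generator enforces its contracts", {
  expect_error(sim_movie_config(class_props = c(I = 0.4, II = 0.2, III = 0.2,
                                                IV = 0.05, V = 0.05)), "sum to 1")
  expect_error(sim_movie_config(noise_sd = -0.1), ">= 0")
  expect_error(sim_movie_config(gap_s = 1), "overlap")
})

test_that("generated movies realize their class definitions", {
  gm <- generate_movie(tiny_movie_config(), seed = 2)
  tr <- gm$truth$rois
  expect_true(all(tr$amp_es2[tr$cls == "I"] == 0))
  expect_true(all(tr$amp_es1[tr$cls == "V"] == 0))
  both <- tr[tr$cls %in% c("II", "III", "IV"), ]
  r <- both$true_ratio
  expect_true(all(r[both$cls == "II"] < 0.8 & r[both$cls == "II"] > 0))
  expect_true(all(r[both$cls == "III"] >= 0.8 & r[both$cls == "III"] <= 1.2))
  expect_true(all(r[both$cls == "IV"] > 1.2))
  # rendered somas do not overlap
  d <- as.matrix(dist(cbind(tr$cx_um, tr$cy_um)))
  diag(d) <- Inf
  lim <- outer(tr$long_um, tr$long_um, `+`) / 2
  expect_true(all(d > lim))
})

test_that("motility generator honours rate, depth and flatness contracts", {
  g <- generate_motility_map(sim_motility_config(rate_per_min = 0.4), seed = 1)
  expect_equal(g$truth$n_events, 6)
  expect_true(all(g$map$D >= 0))
  expect_equal(min(g$map$D), 3 * (1 - 0.4))

  flat <- generate_motility_map(sim_motility_config(rate_per_min = 0), seed = 1)
  expect_true(all(flat$map$D == 3))
})

test_that("projection generator reproduces labelling counts and mixtures", {
  g <- generate_projections(seed = 1)
  tab <- table(g$neurons$region)
  expect_equal(as.integer(tab[c("proximal", "distal")]), c(57L, 61L))
  expect_true(all(g$neurons$length_mm[!is.na(g$neurons$length_mm)] > 0))
  expect_true(all(g$neurons$orientation %in%
                    c("oral", "aboral", "circumferential", "untraceable")))
  expect_true(all(is.na(g$neurons$length_mm[g$neurons$orientation == "untraceable"])))

  # weight (1, 0) puts every draw in component 1
  cfg <- sim_projection_config(mix_weights = c(1, 0), mix_means = c(2, 50),
                               mix_sds = c(0.5, 1))
  g1 <- generate_projections(cfg, seed = 2)
  expect_true(all(g1$neurons$length_mm < 10, na.rm = TRUE))
  expect_error(sim_projection_config(mix_sds = c(0, 1)), "> 0")
})

test_that("ground truth serializes alongside generated data", {
  gm <- generate_movie(tiny_movie_config(), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gm$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$rois), nrow(gm$truth$rois))
  expect_equal(back$rois$cx_um, gm$truth$rois$cx_um, tolerance = 1e-12)
  expect_true(all(back$rois$cls %in% c("I", "II", "III", "IV", "V")))
})
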
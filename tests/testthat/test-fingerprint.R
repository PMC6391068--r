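test_that("amplitude ratio is the plain quotient and rejects inconsistent input", {
  expect_equal(amplitude_ratio(0.4, 0.2), 0.5)
  expect_equal(amplitude_ratio(0.3, 0.3), 1.0)
  expect_error(amplitude_ratio(0, 0.2), "> 0")
})

test_that("signature classification partitions all responder patterns", {
  expect_equal(classify_signature(TRUE, FALSE), "I")
  expect_equal(classify_signature(FALSE, TRUE), "V")
  expect_equal(classify_signature(TRUE, TRUE, 1.0), "III")
  expect_equal(classify_signature(TRUE, TRUE, 0.5), "II")
  expect_equal(classify_signature(TRUE, TRUE, 1.5), "IV")
  # boundary ratios belong to the closed "unchanged" interval
  expect_equal(classify_signature(TRUE, TRUE, 0.8), "III")
  expect_equal(classify_signature(TRUE, TRUE, 1.2), "III")
  expect_error(classify_signature(FALSE, FALSE), "neither")
  expect_error(classify_signature(TRUE, TRUE), "ratio required")
})

test_that("classification is a total partition over random responder pairs", {
  set.seed(21)
  for (i in 1:200) {
    r1 <- runif(1) < 0.8
    r2 <- runif(1) < 0.8
    if (!r1 && !r2) next
    ratio <- if (r1 && r2) rexp(1) else NA_real_
    cls <- classify_signature(r1, r2, ratio)
    expect_true(cls %in% c("I", "II", "III", "IV", "V"))
    if (r1 && r2) expect_true(cls %in% c("II", "III", "IV"))
  }
})

test_that("AoT image carries amplitudes of responders only, max on overlap", {
  m <- flat_movie(value = 100, n_epochs = 2, tn = 16)
  rois <- dplyr::bind_rows(
    disc_roi(1, cx = 25, cy = 40, diam = 25),
    disc_roi(2, cx = 40, cy = 40, diam = 25)  # overlaps ROI 1
  )
  responses <- tibble::tibble(
    roi_id = c(1, 2, 1, 2), stim_index = c(1, 1, 2, 2),
    f0 = 100, amplitude = c(0.3, 0.5, 0.2, 0.1),
    baseline_sd = 0, responded = c(TRUE, TRUE, FALSE, FALSE)
  )
  aot <- build_aot(m, rois, responses, 1)
  expect_equal(max(aot), 0.5)
  expect_true(all(aot %in% c(0, 0.3, 0.5)))
  px1 <- which(aot == 0.3 | aot == 0.5)
  expect_gt(length(px1), 0)
  # overlap pixels take the larger amplitude
  aot_solo <- build_aot(m, rois[2, ], responses[responses$roi_id == 2, ], 1)
  expect_true(all(aot[aot_solo == 0.5] == 0.5))

  # no responders -> all-zero image
  aot2 <- build_aot(m, rois, responses, 2)
  expect_true(all(aot2 == 0))
  expect_error(build_aot(m, rois, responses, 3), "out of range")
})

test_that("ratio histogram bins by 0.2, pools the top bin and sums to 100", {
  recs <- tibble::tibble(
    roi_id = 1:4, amp_es1 = 1, amp_es2 = 1,
    ratio = c(0.5, 1.0, 1.0, 1.5),
    cls = factor(c("II", "III", "III", "IV"), levels = c("I", "II", "III", "IV", "V")),
    condition_pair = "Ctrl-Ctrl", prep_id = 1
  )
  h <- ratio_histogram(recs)
  expect_equal(h$pct[h$bin == "[0.4,0.6)"], 25)
  expect_equal(h$pct[h$bin == "[1.0,1.2)"], 50)
  expect_equal(h$pct[h$bin == "[1.4,1.6)"], 25)
  expect_equal(sum(h$pct), 100)

  # a ratio of exactly 0.8 falls in [0.8, 1.0)
  recs$ratio <- c(0.8, 0.8, 0.8, 0.8)
  h2 <- ratio_histogram(recs)
  expect_equal(h2$pct[h2$bin == "[0.8,1.0)"], 100)

  # a single blocked neuron occupies the categorical bin entirely
  recs3 <- recs[1, ]
  recs3$ratio <- NA_real_
  recs3$cls <- factor("I", levels = levels(recs$cls))
  h3 <- ratio_histogram(recs3)
  expect_equal(h3$pct[h3$bin == "blocked"], 100)

  # ratios above the cap are pooled
  recs$ratio <- c(2.5, 9, 2.41, 0.5)
  h4 <- ratio_histogram(recs)
  expect_equal(h4$n[h4$bin == "2.4+"], 3)
  expect_error(ratio_histogram(recs[0, ]), "no signature")
})

test_that("class summary averages per-preparation percentages with SEM", {
  mk <- function(prep, classes) tibble::tibble(
    roi_id = seq_along(classes), amp_es1 = 1, amp_es2 = 1, ratio = NA_real_,
    cls = factor(classes, levels = c("I", "II", "III", "IV", "V")),
    condition_pair = "Ctrl-Hex", prep_id = prep
  )
  one <- mk(1, c(rep("I", 3), rep("III", 7)))
  s1 <- summarize_classes(one)
  expect_equal(s1$mean_pct[s1$cls == "I"], 30)

  two <- dplyr::bind_rows(mk(1, c("I", rep("III", 9))),
                          mk(2, c(rep("I", 3), rep("III", 7))))
  s2 <- summarize_classes(two)
  expect_equal(s2$mean_pct[s2$cls == "I"], 20)
  expect_equal(s2$sem_pct[s2$cls == "I"], 10)
  expect_equal(s2$n_preps[s2$cls == "I"], 2)
})

test_that("pipeline classes on a noise-free movie match ground truth and sum to responders", {
  gm <- generate_movie(tiny_movie_config(), seed = 4)
  fp <- fingerprint_pipeline(gm$movie, gm$truth$rois)
  expect_equal(class_accuracy(gm$truth, fp$signatures), 1)
  expect_equal(sum(table(fp$signatures$cls)), nrow(fp$signatures))
})
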
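test_that("orientation sectors partition the half-circle at 45 and 135 degrees", {
  oral <- c(-1, 0)
  expect_equal(classify_orientation(c(-1, 0), oral), "oral")        # 0 deg
  expect_equal(classify_orientation(c(1, 0), oral), "aboral")       # 180 deg
  expect_equal(classify_orientation(c(0, 1), oral), "circumferential")  # 90 deg
  expect_equal(classify_orientation(c(-1, 1), oral), "oral")        # exactly 45
  expect_equal(classify_orientation(c(1, 1), oral), "aboral")       # exactly 135
  expect_error(classify_orientation(c(0, 0), oral), "non-zero")
  # every direction gets exactly one label
  for (th in seq(0, pi, length.out = 37)) {
    v <- c(cos(th), sin(th))
    expect_true(classify_orientation(v, c(1, 0)) %in%
                  c("oral", "aboral", "circumferential"))
  }
})

test_that("the bimodal mixture fit recovers well-separated components", {
  set.seed(42)
  x <- rmix_lengths(2000, c(1.5, 5.0), c(0.4, 1.0), c(0.5, 0.5))
  fit <- fit_bimodal(x, seed = 1)
  expect_true(fit$bimodal)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - 1.5), 0.15)
  expect_lt(abs(fit$means[2] - 5.0), 0.15)
  expect_gt(fit$trough_mm, fit$means[1])
  expect_lt(fit$trough_mm, fit$means[2])
  # label invariance: components come back ordered by mean
  expect_lt(fit$means[1], fit$means[2])
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(43)
  x <- rmix_lengths(1500, c(1.8, 4.8), c(0.6, 1.0), c(0.55, 0.45))
  fit <- fit_bimodal(x, seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mc_means <- sort(mc$parameters$mean)
  expect_lt(max(abs(fit$means - mc_means)), 0.05)
  expect_gte(fit$loglik, mc$loglik - 0.5)
})

test_that("degenerate and invalid inputs are handled", {
  set.seed(44)
  uni <- rnorm(500, 3, 0.5)
  fit <- fit_bimodal(uni, seed = 1)
  expect_false(fit$bimodal)
  expect_true(is.na(fit$trough_mm))
  expect_error(fit_bimodal(c(1, 2, 3)), "at least 4")
  expect_error(fit_bimodal(c(1, 2, -1, 3)), "> 0")
})

test_that("splitting at the cutoff assigns the cutoff itself to long", {
  sp <- split_by_cutoff(c(1, 2, 4, 5), 3.1)
  expect_equal(sp$short, c(1, 2))
  expect_equal(sp$long, c(4, 5))
  expect_equal(split_by_cutoff(c(3.1), 3.1)$long, 3.1)
  sp0 <- split_by_cutoff(numeric(0), 3.1)
  expect_length(sp0$short, 0)
  expect_length(sp0$long, 0)
  # partition property
  set.seed(45)
  x <- rexp(100, 0.3)
  sp2 <- split_by_cutoff(x, 2)
  expect_equal(length(sp2$short) + length(sp2$long), 100)
  expect_error(split_by_cutoff(x, 0), "> 0")
})

test_that("the 2x2 chi-square test matches hand-computed tables", {
  same <- compare_proportions(10, 20, 10, 20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  t2 <- compare_proportions(30, 40, 10, 40)
  expect_equal(t2$statistic, 20, tolerance = 1e-9)

  t3 <- compare_proportions(0, 10, 10, 10)
  expect_gt(t3$statistic, 10)
  expect_lt(t3$p_value, 0.01)
  expect_error(compare_proportions(1, 0, 1, 2), "> 0")
  expect_error(compare_proportions(5, 4, 1, 2), "0 <= k <= n")
})

test_that("mixture recovery improves with sample size", {
  bias_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      x <- rmix_lengths(n, c(1.5, 5.0), c(0.4, 1.0), c(0.5, 0.5))
      fit <- fit_bimodal(x, restarts = 5, seed = s)
      mean(abs(fit$means - c(1.5, 5.0)))
    }, numeric(1)))
  }
  expect_lt(bias_at(2000, 1:8), bias_at(100, 1:8))
})
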
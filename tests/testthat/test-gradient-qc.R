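# Profile extraction, shape classification and replicate reproducibility.

test_that("a vertical ramp image extracts to the exact unit ramp", {
  img <- matrix(rep(seq(0, 1, length.out = 50L), 30L), ncol = 30L)
  p <- extract_profile(img)
  expect_true(attr(p, "normalized"))
  expect_lt(max(abs(p$intensity - p$depth)), 1e-6)
})

test_that("a uniform image is flagged constant and left un-normalized", {
  p <- extract_profile(matrix(0.4, 20L, 10L))
  expect_false(attr(p, "normalized"))
  expect_identical(attr(p, "raw_range"), 0)
  expect_true(all(p$intensity == 0.4))
})

test_that("ROIs are validated", {
  img <- matrix(runif(200), 20L)
  expect_error(extract_profile(img, roi = c(15L, 1L, 10L, 5L)), "roi")
  expect_error(extract_profile(img, roi = c(1L, 1L, 0L, 5L)), "roi")
})

test_that("rendered profiles round-trip through extraction", {
  base <- generate_gradient_replicates(1L, "sigmoid", 80L, 0, seed = 2L)[[1L]]
  img <- render_profile_image(base, width_px = 50L, pixel_noise_sd = 0.01,
                              seed = 3L)
  got <- extract_profile(img)
  expect_lt(max(abs(got$intensity - base$intensity)), 0.02)
})

test_that("noiseless generator shapes classify to their own class", {
  expect_identical(
    classify_profile(generate_gradient_replicates(1L, "step", 101L, 0, 1L)[[1L]]),
    "step")
  expect_identical(
    classify_profile(generate_gradient_replicates(1L, "linear", 101L, 0, 1L)[[1L]]),
    "smooth")
  expect_identical(
    classify_profile(generate_gradient_replicates(1L, "sigmoid", 101L, 0, 1L)[[1L]]),
    "smooth")
  expect_identical(
    classify_profile(generate_gradient_replicates(1L, "uniform", 101L, 0, 1L)[[1L]]),
    "uniform")
  expect_error(
    classify_profile(gradient_profile(c(0, 0.5, 1), c(0, 0.5, 1))),
    "4 points")
})

test_that("generate -> render -> extract -> classify recovers each shape", {
  for (shape in c("step", "linear", "sigmoid", "uniform")) {
    base <- generate_gradient_replicates(1L, shape, 80L, 0.02, seed = 7L)[[1L]]
    img <- render_profile_image(base, width_px = 60L, seed = 8L)
    got <- extract_profile(img)
    expected <- if (shape %in% c("linear", "sigmoid")) "smooth" else shape
    expect_identical(classify_profile(got), expected)
  }
})

test_that("identical replicates have zero deviation", {
  p <- generate_gradient_replicates(1L, "linear", 40L, 0, seed = 1L)[[1L]]
  rep_ <- mean_absolute_deviation(list(p, p, p))
  expect_identical(rep_$mean_mad, 0)
  expect_identical(rep_$sd_mad, 0)
  expect_identical(rep_$n_replicates, 3L)
})

test_that("two constant profiles at 0.4 and 0.6 deviate by 10% each", {
  d <- seq(0, 1, length.out = 20L)
  a <- gradient_profile(d, rep(0.4, 20L), normalized = FALSE, raw_range = 0)
  b <- gradient_profile(d, rep(0.6, 20L), normalized = FALSE, raw_range = 0)
  rep_ <- mean_absolute_deviation(list(a, b))
  expect_equal(rep_$per_replicate_mad, c(10, 10))
  expect_equal(rep_$mean_mad, 10)
})

test_that("deviation report is invariant to replicate order", {
  profs <- generate_gradient_replicates(6L, "linear", 51L, 0.05, seed = 12L)
  r1 <- mean_absolute_deviation(profs)
  r2 <- mean_absolute_deviation(rev(profs))
  expect_equal(r1$mean_mad, r2$mean_mad)
  expect_equal(sort(r1$per_replicate_mad), sort(r2$per_replicate_mad))
  expect_error(mean_absolute_deviation(profs[1L]), "at least 2")
})

test_that("profiles on different grids are interpolated to a common one", {
  a <- gradient_profile(seq(0, 1, length.out = 41L),
                        seq(0, 1, length.out = 41L))
  b <- gradient_profile(seq(0, 1, length.out = 61L),
                        seq(0, 1, length.out = 61L))
  rep_ <- mean_absolute_deviation(list(a, b))
  expect_lt(rep_$mean_mad, 1e-9)
})
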
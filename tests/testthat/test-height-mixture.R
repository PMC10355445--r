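# Empirical CDF construction, the mixture model CDF, and the
# least-squares mixture fit.

test_that("empirical CDF assigns rank/n and collapses ties upward", {
  z <- matrix(rep(c(1, 2, 3), length.out = 120), 12)
  ec <- empirical_cdf(height_map(z, 1))
  expect_equal(ec$F[ec$z_sorted == 2], 2 / 3)
  expect_equal(ec$F[length(ec$F)], 1)

  const <- empirical_cdf(height_map(matrix(5, 10, 10), 1))
  expect_identical(const$z_sorted, 5)
  expect_identical(const$F, 1)
})

test_that("empirical CDF refuses maps under 100 pixels", {
  expect_error(empirical_cdf(height_map(matrix(rnorm(99), 9, 11), 1)),
               "at least 100")
})

test_that("empirical CDF of normal draws meets the DKW band", {
  set.seed(19L)
  hm <- height_map(matrix(rnorm(10000), 100), 1)
  ec <- empirical_cdf(hm)
  # DKW: P(sup|F_n - F| > eps) <= 2 exp(-2 n eps^2); eps = 0.02 at
  # n = 10,000 is exceeded with probability < 7e-4
  expect_lt(max(abs(ec$F - pnorm(ec$z_sorted))), 0.02)
})

test_that("model CDF evaluates the mixture and normalizes", {
  th1 <- mixture_params(1, 0, 0, 0, 0, 0, 1, 1, 1)
  expect_equal(model_cdf(th1, 0), 0.5)
  th2 <- mixture_params(0.4, 0.35, 0.25, -1, 0.5, 3, 0.2, 0.4, 0.8)
  expect_equal(model_cdf(th2, Inf), 1)
  expect_equal(model_cdf(th2, -Inf), 0)
  # Phi(1) + Phi(-1) = 1, halved and summed
  th3 <- mixture_params(0.5, 0.5, 0, 0, 2, 2, 1, 1, 1)
  expect_equal(model_cdf(th3, 1), 0.5)
})

test_that("model CDF is monotone for random valid parameter sets", {
  set.seed(23L)
  z <- seq(-5, 10, length.out = 300)
  for (i in 1:20) {
    p <- as.vector(stats::rmultinom(1, 1000, runif(3))) / 1000
    mu <- sort(runif(3, -2, 6))
    sg <- runif(3, 0.05, 2)
    th <- mixture_params(p[1], p[2], p[3], mu[1], mu[2], mu[3],
                         sg[1], sg[2], sg[3])
    expect_true(all(diff(model_cdf(th, z)) >= 0))
  }
})

test_that("mixture params enforce their invariants", {
  expect_error(mixture_params(0.5, 0.4, 0.2, 0, 1, 2, 1, 1, 1), "sum to 1")
  expect_error(mixture_params(0.5, 0.3, 0.2, 2, 1, 0, 1, 1, 1), "mu_mica")
  expect_error(mixture_params(0.5, 0.3, 0.2, 0, 1, 2, 0, 1, 1), "sigmas")
})

test_that("fit recovers ground-truth fractions on separated scenes", {
  for (s in 1:3) {
    sc <- generate_afm_scene(mixture_scene_spec(s))
    fit <- fit_height_mixture(sc$map, n_restarts = 3L, seed = s)
    expect_true(fit$converged)
    expect_equal(sum(fit$params$p), 1, tolerance = 1e-9)
    expect_true(all(fit$params$p >= 0 & fit$params$p <= 1))
    expect_lt(max(abs(fit$params$p - sc$truth$pixel_fractions)), 0.03)
  }
})

test_that("single-population map collapses onto the mica component", {
  set.seed(31L)
  hm <- height_map(matrix(rnorm(10000, 0, 0.1), 100), 4)
  fit <- fit_height_mixture(hm, n_restarts = 3L, seed = 2L)
  expect_lt(abs(fit$params$p["mica"] - 1), 0.02)
})

test_that("constant maps are refused", {
  expect_error(fit_height_mixture(height_map(matrix(2, 20, 20), 1)),
               "constant")
})

test_that("canonicalization is invariant to component order", {
  p <- c(0.2, 0.5, 0.3); mu <- c(3, -1, 0.5); sg <- c(0.4, 0.1, 0.2)
  ref <- rzcpurity:::canonical_params(p, mu, sg)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(rzcpurity:::canonical_params(p[perm], mu[perm], sg[perm]), ref)
  }
})

test_that("fitted fractions agree with a brute-force lattice search", {
  # two-population sample; oracle: exhaustive coarse lattice over
  # (p, mu1, mu2, sigma) with a shared SD, minimizing the same CDF SSE
  set.seed(47L)
  z <- c(rnorm(7000, 0, 0.15), rnorm(3000, 1.5, 0.15))
  hm <- height_map(matrix(z, 100), 1)
  ec <- empirical_cdf(hm, max_points = 4000L, seed = 1L)

  best <- NULL
  for (p1 in seq(0.1, 0.9, by = 0.05)) {
    for (m1 in seq(-0.2, 0.4, by = 0.1)) {
      for (m2 in seq(1.1, 1.9, by = 0.1)) {
        for (sg in c(0.1, 0.15, 0.2, 0.3)) {
          mdl <- p1 * pnorm(ec$z_sorted, m1, sg) +
            (1 - p1) * pnorm(ec$z_sorted, m2, sg)
          sse <- sum((mdl - ec$F)^2)
          if (is.null(best) || sse < best$sse) {
            best <- list(sse = sse, p1 = p1)
          }
        }
      }
    }
  }

  fit <- fit_height_mixture(hm, n_restarts = 3L, seed = 1L)
  # group fitted mass below/above the midpoint between oracle means
  low_mass <- sum(fit$params$p[fit$params$mu < 0.75])
  expect_lt(abs(low_mass - best$p1), 0.05)
})

test_that("staple reduction is the before/after fraction ratio", {
  expect_equal(staple_reduction(0.62, 0.29), 0.62 / 0.29)
  expect_equal(round(staple_reduction(0.62, 0.29), 2), 2.14)
  expect_equal(staple_reduction(0.4, 0.4), 1)
  expect_equal(staple_reduction(0.5, 0.25), 2)
  expect_error(staple_reduction(0.5, 0), "near zero")
  bad <- structure(list(converged = FALSE,
                        params = mixture_params(0.3, 0.3, 0.4, 0, 1, 2, 1, 1, 1)),
                   class = "mixture_fit")
  expect_error(staple_reduction(bad, 0.2), "converge")
})

test_that("height maps round-trip through TIFF and text formats", {
  sc <- generate_afm_scene(scene_spec(width_px = 64L, height_px = 64L,
                                      n_monomers = 0L, n_dimers = 0L,
                                      n_staples = 30L, seed = 2L))
  tf <- withr::local_tempfile(fileext = ".tif")
  write_height_map(sc$map, tf)
  back <- read_height_map(tf)
  expect_equal(back$heights, sc$map$heights, tolerance = 1e-6)
  expect_identical(back$nm_per_pixel, sc$map$nm_per_pixel)

  tx <- withr::local_tempfile(fileext = ".txt")
  write_height_map_txt(sc$map, tx)
  back2 <- read_height_map_txt(tx)
  expect_equal(back2$heights, sc$map$heights, tolerance = 1e-12)
})
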
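# Generators: seeded determinism, ground-truth consistency, and the
# statistical structure each downstream stage assumes.

test_that("empty scene is all mica with exact unit fractions", {
  sp <- scene_spec(width_px = 32L, height_px = 32L, n_monomers = 0L,
                   n_dimers = 0L, n_staples = 0L, seed = 3L)
  sc <- generate_afm_scene(sp)
  expect_true(all(sc$truth$class_map == 0L))
  expect_identical(unname(sc$truth$pixel_fractions), c(1, 0, 0))
  expect_equal(dim(sc$map$heights), c(32L, 32L))
})

test_that("identical spec including seed gives bit-identical scenes", {
  sp <- scene_spec(width_px = 96L, height_px = 96L, n_monomers = 1L,
                   n_dimers = 0L, n_staples = 50L, seed = 7L)
  a <- generate_afm_scene(sp)
  b <- generate_afm_scene(sp)
  expect_identical(a$map$heights, b$map$heights)
  expect_identical(a$truth$class_map, b$truth$class_map)
  expect_identical(a$truth$particles, b$truth$particles)
})

test_that("ground-truth fractions match the class map and sum to one", {
  for (s in 1:5) {
    sc <- generate_afm_scene(scene_spec(width_px = 128L, height_px = 128L,
                                        n_monomers = 2L, n_dimers = 0L,
                                        n_staples = 200L, seed = s))
    counts <- tabulate(sc$truth$class_map + 1L, nbins = 3L)
    expect_identical(sum(sc$truth$pixel_fractions), 1)
    expect_equal(unname(sc$truth$pixel_fractions), counts / sum(counts),
                 tolerance = 1e-12)
  }
})

test_that("staple count chosen for ~30% coverage lands within 0.05", {
  # plus-blobs cover ~5 px each; random overlap thins coverage like
  # 1 - exp(-k a / N), so invert that for the target fraction
  n_px <- 224L * 224L
  n_staples <- round(-log(1 - 0.3) * n_px / 5)
  sp <- scene_spec(width_px = 224L, height_px = 224L, n_monomers = 0L,
                   n_dimers = 0L, n_staples = n_staples, seed = 11L)
  sc <- generate_afm_scene(sp)
  expect_lt(abs(sc$truth$pixel_fractions["staple"] - 0.3), 0.05)
})

test_that("tubes that cannot fit raise a placement error", {
  sp <- scene_spec(width_px = 40L, height_px = 40L, nm_per_pixel = 4,
                   n_monomers = 1L, n_dimers = 0L, n_staples = 0L, seed = 1L)
  # 460 nm tube needs ~115 px; a 40 px field cannot hold it
  expect_error(generate_afm_scene(sp), "could not place")
})

test_that("scene spec validates its invariants", {
  expect_error(scene_spec(mica_mu = 1, staple_mu = 0.5), "mica_mu < staple_mu")
  expect_error(scene_spec(monomer_len_nm = 900, dimer_len_nm = 800),
               "monomer_len_nm")
  expect_error(scene_spec(noise_sigma = 0), "noise_sigma")
  expect_error(scene_spec(width_px = 0), "width_px")
})

test_that("length sample has exactly round-half-up dimer counts", {
  s0 <- generate_length_sample(10L, 0, seed = 1L)
  expect_identical(sum(s0$label == "dimer"), 0L)
  expect_identical(sum(s0$label == "monomer"), 10L)

  s1 <- generate_length_sample(273L, 0.21, seed = 1L)
  expect_identical(sum(s1$label == "dimer"), 57L)  # round(273 * 0.21 = 57.33)

  # property: count = floor(n * f + 0.5) across a grid
  for (n in c(2L, 7L, 50L, 114L, 273L)) {
    for (f in c(0, 0.1, 0.21, 0.5, 0.63, 0.9, 1)) {
      s <- generate_length_sample(n, f, seed = n + round(100 * f))
      expect_identical(sum(s$label == "dimer"), as.integer(floor(n * f + 0.5)))
    }
  }
})

test_that("zero length variation gives exact class lengths", {
  s <- generate_length_sample(100L, 0.5, monomer_len_nm = 460,
                              dimer_len_nm = 920, length_cv = 0, seed = 2L)
  expect_identical(sort(unique(s$length_nm)), c(460, 920))
  expect_true(all(s$length_nm[s$label == "dimer"] == 920))
})

test_that("length sample validates inputs and is seeded-deterministic", {
  expect_error(generate_length_sample(0L, 0.5), "n")
  expect_error(generate_length_sample(10L, 1.5), "dimer_fraction")
  a <- generate_length_sample(50L, 0.3, seed = 9L)
  b <- generate_length_sample(50L, 0.3, seed = 9L)
  expect_identical(a, b)
})

test_that("gradient base shapes are correct at zero noise", {
  u <- generate_gradient_replicates(2L, "uniform", n_points = 21L,
                                    noise_sd = 0, seed = 1L)
  expect_true(all(u[[1L]]$intensity == u[[1L]]$intensity[1L]))

  l <- generate_gradient_replicates(1L, "linear", n_points = 21L,
                                    noise_sd = 0, seed = 1L)
  expect_identical(l[[1L]]$intensity[11L], 0.5)  # midpoint of the unit ramp
  expect_identical(l[[1L]]$intensity, l[[1L]]$depth)

  s <- generate_gradient_replicates(1L, "step", n_points = 20L,
                                    noise_sd = 0, seed = 1L)
  expect_identical(sort(unique(s[[1L]]$intensity)), c(0, 1))

  expect_error(generate_gradient_replicates(1L, "spiral"), "arg")
})

test_that("replicate deviation of noisy ramps matches a simulation oracle", {
  n_rep <- 20L; n_pt <- 101L; sd_noise <- 0.05
  profs <- generate_gradient_replicates(n_rep, "linear", n_pt, sd_noise,
                                        seed = 5L)
  got <- mean_absolute_deviation(profs)$mean_mad

  # independent oracle: simulate the same statistic from plain Gaussian
  # noise matrices (the ramp cancels in deviations-from-mean)
  set.seed(401L)
  sim <- replicate(300L, {
    e <- matrix(rnorm(n_pt * n_rep, 0, sd_noise), n_pt, n_rep)
    mean(colMeans(abs(e - rowMeans(e)))) * 100
  })
  expect_lt(abs(got - mean(sim)), 4 * stats::sd(sim))
  # and the closed-form folded-normal mean for deviations from a mean of
  # N replicates: sigma * sqrt(2/pi) * sqrt((N-1)/N), in percent
  expect_lt(abs(mean(sim) - 100 * sd_noise * sqrt(2 / pi) * sqrt(19 / 20)),
            4 * stats::sd(sim) / sqrt(300))
})

test_that("gradient replicates are seeded-deterministic", {
  a <- generate_gradient_replicates(3L, "sigmoid", 51L, 0.02, seed = 13L)
  b <- generate_gradient_replicates(3L, "sigmoid", 51L, 0.02, seed = 13L)
  expect_identical(a, b)
})
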
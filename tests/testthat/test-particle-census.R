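# Detection, contour-length measurement, classification and the census.

test_that("background-only scenes yield no particles", {
  sp <- scene_spec(width_px = 128L, height_px = 128L, n_monomers = 0L,
                   n_dimers = 0L, n_staples = 100L, seed = 4L)
  sc <- generate_afm_scene(sp)
  expect_length(detect_particles(sc$map, CENSUS_THRESHOLD_NM, 20L), 0L)
  # a threshold above every pixel is vacuous
  expect_length(
    detect_particles(sc$map, max(sc$map$heights) + 1, 1L), 0L
  )
})

test_that("non-overlapping tubes are detected one-to-one", {
  sc <- generate_afm_scene(census_scene_spec(5L, 0L, seed = 8L))
  parts <- detect_particles(sc$map, CENSUS_THRESHOLD_NM, 20L)
  expect_length(parts, 5L)
  # deterministic ordering by centroid
  rows <- vapply(parts, function(p) p$centroid[["row"]], 0)
  expect_identical(order(rows), seq_along(rows))
})

test_that("contour length of axis-aligned and bent rods is the path length", {
  # 51 px horizontal rod at 10 nm/px: 50 steps = 500 nm (exact for 1 px
  # thickness; tolerance one pixel)
  rod <- make_particle(rep(5L, 51L), 10L:60L)
  expect_lt(abs(measure_contour_length(rod, 10) - 500), 10)

  # single pixel: zero length with a warning
  expect_warning(l1 <- measure_contour_length(make_particle(3L, 3L), 10))
  expect_identical(l1, 0)

  # L-shape, two 11 px arms sharing a corner: longest path 20 steps = 200 nm
  ell <- make_particle(c(rep(10L, 11L), 11L:20L), c(10L:20L, rep(20L, 10L)))
  expect_lt(abs(measure_contour_length(ell, 10) - 200), 20)
})

test_that("axis-aligned thin rods measure exactly (n_px - 1) * nm_per_pixel", {
  for (n in c(11L, 34L, 101L)) {
    rod <- make_particle(20L:(19L + n), rep(7L, n))
    expect_identical(measure_contour_length(rod, 4), (n - 1) * 4)
  }
})

test_that("length classification uses the documented windows", {
  expect_identical(classify_by_length(500), "monomer")
  expect_identical(classify_by_length(1000), "dimer")
  expect_identical(classify_by_length(750), "dimer")   # boundary -> dimer
  expect_identical(classify_by_length(120), "other")
  expect_identical(classify_by_length(c(250, 249.9, 1500, 1500.1)),
                   c("monomer", "other", "dimer", "other"))
  expect_error(classify_by_length(-5), "finite")
  expect_error(classify_by_length(500, window = 0.6), "window")
})

test_that("census counts and fractions follow the label vector", {
  cen <- census(c("monomer", "monomer", "dimer"))
  expect_identical(cen$n_monomer, 2L)
  expect_equal(cen$dimer_fraction, 1 / 3)
  expect_equal(cen$monomer_fraction + cen$dimer_fraction, 1)

  empty <- census(character(0))
  expect_identical(empty$n_monomer, 0L)
  expect_true(is.na(empty$dimer_fraction))

  other_only <- census(c("other", "other"))
  expect_true(is.na(other_only$dimer_fraction))

  # permutation invariance
  labs <- c(rep("monomer", 5), rep("dimer", 3), "other")
  expect_identical(census(labs), census(rev(labs)))
})

test_that("classifying a generated length sample recovers its composition", {
  s <- generate_length_sample(273L, 0.21, length_cv = 0.05, seed = 6L)
  cen <- census(classify_by_length(s$length_nm))
  expect_lt(abs(cen$dimer_fraction - 57 / 273), 0.02)
})

test_that("detect-measure-classify recovers scene composition end-to-end", {
  for (cfg in list(c(6L, 2L, 21L), c(2L, 6L, 22L), c(4L, 4L, 23L))) {
    sc <- generate_afm_scene(census_scene_spec(cfg[1L], cfg[2L], cfg[3L]))
    out <- census_height_map(sc$map, CENSUS_THRESHOLD_NM, min_area_px = 20L)
    truth_frac <- cfg[2L] / (cfg[1L] + cfg[2L])
    expect_lt(abs(out$census$dimer_fraction - truth_frac), 0.05)
  }
})

test_that("predicted contour lengths follow the helix rise arithmetic", {
  expect_equal(predict_contour_length(32, 42, 0.34), 456.96)
  expect_equal(predict_contour_length(64 + 2 / 3, 42, 0.34), 923.44,
               tolerance = 1e-12)
  expect_identical(predict_contour_length(0, 42, 0.34), 0)
  expect_identical(present_length_nm(456.96), 460)
  expect_identical(present_length_nm(923.44), 920)
})
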
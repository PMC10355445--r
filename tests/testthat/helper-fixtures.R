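# Shared fixture builders. All synthetic, generated at test time.

# AFM scene with paper-like coverage (staple ~30%, origami ~5% of pixels)
# and component separation >= 3x the largest SD, for mixture-recovery
# checks. 224 x 224 px ~ 50k pixels.
mixture_scene_spec <- function(seed, width_px = 224L, height_px = 224L) {
  scene_spec(
    width_px = width_px, height_px = height_px, nm_per_pixel = 4,
    mica_mu = 0, staple_mu = 1, origami_mu = 2.5,
    mica_sigma = 0.1, staple_sigma = 0.15, origami_sigma = 0.3,
    n_monomers = 12L, n_dimers = 0L, n_staples = 3200L,
    noise_sigma = 0.05, seed = seed
  )
}

# Scene for the detection/census pipeline: default heights, a handful of
# well-separated tubes in a 2.4 x 2.4 um field.
census_scene_spec <- function(n_monomers, n_dimers, seed) {
  scene_spec(
    width_px = 600L, height_px = 600L, nm_per_pixel = 4,
    n_monomers = n_monomers, n_dimers = n_dimers, n_staples = 300L,
    seed = seed
  )
}

# Height threshold for census scenes, on the 3x3-smoothed map: ~2 SD
# above the smoothed staple level (~0.3 nm) and ~6 SD below the smoothed
# tube interior (~1.3 nm). Kept near the staple side because tube
# dropouts fragment particles while staple exceedances are removed by
# the minimum-area filter.
CENSUS_THRESHOLD_NM <- 0.5

# Build a particle object directly from pixel coordinates (rows, cols).
make_particle <- function(rows, cols) {
  px <- cbind(row = as.integer(rows), col = as.integer(cols))
  structure(
    list(pixels = px,
         centroid = c(row = mean(px[, "row"]), col = mean(px[, "col"])),
         area_px = nrow(px)),
    class = "particle"
  )
}
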
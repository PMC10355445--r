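#!/usr/bin/env Rscript
# Simulate the AFM fields the purification comparison needs: an
# "unpurified" scene crowded with excess staple strands and a "purified"
# scene where most staples are gone, plus the dilute fields used for
# monomer/dimer counting. Writes the height maps and their ground truth
# under results/analysis/.

suppressPackageStartupMessages(library(rzcpurity))

outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# mixture fields: 224 x 224 px at 4 nm/px (~0.9 x 0.9 um), staple coverage
# ~30% before and ~6% after purification, a dozen nanotubes each
unpurified <- generate_afm_scene(scene_spec(
  width_px = 224L, height_px = 224L, nm_per_pixel = 4,
  staple_mu = 1, origami_mu = 2.5,
  mica_sigma = 0.1, staple_sigma = 0.15, origami_sigma = 0.3,
  n_monomers = 12L, n_dimers = 0L, n_staples = 3200L,
  noise_sigma = 0.05, seed = 101L
))
purified <- generate_afm_scene(scene_spec(
  width_px = 224L, height_px = 224L, nm_per_pixel = 4,
  staple_mu = 1, origami_mu = 2.5,
  mica_sigma = 0.1, staple_sigma = 0.15, origami_sigma = 0.3,
  n_monomers = 12L, n_dimers = 0L, n_staples = 550L,
  noise_sigma = 0.05, seed = 102L
))

write_height_map(unpurified$map, file.path(outdir, "scene_unpurified.tif"))
write_height_map(purified$map, file.path(outdir, "scene_purified.tif"))

truth <- rbind(
  data.frame(field = "unpurified", t(unpurified$truth$pixel_fractions)),
  data.frame(field = "purified", t(purified$truth$pixel_fractions))
)
write.csv(truth, file.path(outdir, "scene_truth_fractions.csv"),
          row.names = FALSE)

# census fields: 600 x 600 px (2.4 x 2.4 um), sparse tubes; compositions
# mimic the unpurified (~21% dimer) and purified (~63% dimer) samples
census_unpur <- generate_afm_scene(scene_spec(
  width_px = 600L, height_px = 600L, nm_per_pixel = 4,
  n_monomers = 6L, n_dimers = 2L, n_staples = 300L, seed = 111L
))
census_pur <- generate_afm_scene(scene_spec(
  width_px = 600L, height_px = 600L, nm_per_pixel = 4,
  n_monomers = 3L, n_dimers = 5L, n_staples = 60L, seed = 112L
))
write_height_map(census_unpur$map, file.path(outdir, "census_unpurified.tif"))
write_height_map(census_pur$map, file.path(outdir, "census_purified.tif"))

cat("simulated fields written to", outdir, "\n")
cat(sprintf("  unpurified staple coverage: %.1f%%\n",
            100 * unpurified$truth$pixel_fractions["staple"]))
cat(sprintf("  purified staple coverage:   %.1f%%\n",
            100 * purified$truth$pixel_fractions["staple"]))
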
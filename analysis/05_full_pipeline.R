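#!/usr/bin/env Rscript
# One-command reproduction: run every stage from a single seeded config
# and write the combined machine-readable purity report.

suppressPackageStartupMessages(library(rzcpurity))

cfg <- pipeline_config(
  seed = 1L, outdir = "results/pipeline",
  scene_before = scene_spec(width_px = 224L, height_px = 224L,
                            staple_mu = 1, origami_mu = 2.5,
                            mica_sigma = 0.1, staple_sigma = 0.15,
                            origami_sigma = 0.3, n_monomers = 12L,
                            n_dimers = 0L, n_staples = 3200L,
                            noise_sigma = 0.05, seed = 1L),
  scene_after = scene_spec(width_px = 224L, height_px = 224L,
                           staple_mu = 1, origami_mu = 2.5,
                           mica_sigma = 0.1, staple_sigma = 0.15,
                           origami_sigma = 0.3, n_monomers = 12L,
                           n_dimers = 0L, n_staples = 550L,
                           noise_sigma = 0.05, seed = 2L),
  sample_before = list(n = 273L, dimer_fraction = 0.21),
  sample_after = list(n = 114L, dimer_fraction = 0.63),
  gradient = list(n_replicates = 20L, shape = "linear", n_points = 101L,
                  noise_sd = 0.05),
  n_restarts = 3L
)

report <- run_pipeline(cfg)
print(report)
cat("\nartifacts under", cfg$outdir, "\n")
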
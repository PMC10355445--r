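#!/usr/bin/env Rscript
# Decompose the pixel-height distribution of each simulated field into
# mica / staple / origami fractions by fitting the three-Gaussian mixture
# CDF, and report the staple-fraction fold reduction achieved by
# purification. Requires 01_simulate_scenes.R to have run.

suppressPackageStartupMessages(library(rzcpurity))

outdir <- "results/analysis"
unpur <- read_height_map(file.path(outdir, "scene_unpurified.tif"))
pur <- read_height_map(file.path(outdir, "scene_purified.tif"))

fit_unpur <- fit_height_mixture(unpur, n_restarts = 3L, seed = 201L)
fit_pur <- fit_height_mixture(pur, n_restarts = 3L, seed = 202L)

write_mixture_fit(fit_unpur, file.path(outdir, "fit_unpurified.json"))
write_mixture_fit(fit_pur, file.path(outdir, "fit_purified.json"))

truth <- read.csv(file.path(outdir, "scene_truth_fractions.csv"))
tab <- data.frame(
  field = c("unpurified", "purified"),
  p_staple_fit = c(fit_unpur$params$p["staple"], fit_pur$params$p["staple"]),
  p_staple_truth = truth$staple,
  p_origami_fit = c(fit_unpur$params$p["origami"], fit_pur$params$p["origami"]),
  p_origami_truth = truth$origami
)
write.csv(tab, file.path(outdir, "mixture_fractions.csv"), row.names = FALSE)

fold <- staple_reduction(fit_unpur, fit_pur)

cat("mixture CDF fits (fractions, fit vs truth):\n")
print(tab, digits = 3, row.names = FALSE)
cat(sprintf("\nstaple fraction reduced by %.2fx after purification\n", fold))
cat(sprintf("(the study reports 2.14x on its own images: 0.62 -> 0.29)\n"))
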
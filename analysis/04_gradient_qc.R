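#!/usr/bin/env Rscript
# Gradient-tube quality control: classify profile shapes across emulated
# spin times (unmixed step, good quasi-linear gradient, over-mixed
# uniform) and quantify run-to-run reproducibility of 20 replicate
# gradients as the mean absolute deviation from the mean profile.

suppressPackageStartupMessages(library(rzcpurity))

outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# shape classification across emulated spin times
shapes <- data.frame(
  condition = c("30 s (under-mixed)", "60 s (target)", "180 s (over-mixed)"),
  generated = c("step", "sigmoid", "uniform")
)
shapes$classified <- vapply(shapes$generated, function(sh) {
  p <- generate_gradient_replicates(1L, sh, n_points = 101L,
                                    noise_sd = 0.02, seed = 401L)[[1L]]
  classify_profile(p)
}, "")
write.csv(shapes, file.path(outdir, "gradient_shapes.csv"), row.names = FALSE)
cat("gradient shape classification:\n")
print(shapes, row.names = FALSE)

# reproducibility of 20 replicate gradients at 5% intensity noise
profs <- generate_gradient_replicates(20L, "linear", n_points = 101L,
                                      noise_sd = 0.05, seed = 402L)
write_gradient_profiles(profs, file.path(outdir, "gradient_profiles.csv"))
rep_ <- mean_absolute_deviation(profs)
write.csv(
  data.frame(replicate = seq_along(rep_$per_replicate_mad),
             mad_pct = rep_$per_replicate_mad),
  file.path(outdir, "gradient_mad.csv"), row.names = FALSE
)
cat(sprintf(
  "\nabsolute deviation from the mean profile: %.1f +/- %.1f%% (mean +/- SD, N = %d)\n",
  rep_$mean_mad, rep_$sd_mad, rep_$n_replicates
))
cat("(the study reports 4.9 +/- 4.7% over 20 tube photographs)\n")
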
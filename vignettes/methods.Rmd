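---
title: "Quantifying DNA origami purity after rate-zonal centrifugation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA origami purity after rate-zonal centrifugation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rzcpurity)
```

## The problem

Rate-zonal centrifugation (RZC) separates DNA origami nanostructures from
excess staple strands — and origami dimers from their precursor monomers —
by sedimenting them through a preformed density gradient. Judging how well
a purification worked requires numbers, and the raw evidence is images:
atomic force microscopy (AFM) height maps of the deposited sample, and
photographs of the gradient tubes themselves. `rzcpurity` implements the
quantitative chain from those images to purity statistics:

1. **Height-mixture decomposition** — what fraction of the imaged surface
   is mica, staple strands, or folded origami?
2. **Particle census** — of the counted nanotubes, what fraction are
   monomers vs dimers?
3. **Resampling** — what is the standard error of such a binary fraction?
4. **Gradient QC** — is the gradient a usable quasi-continuous ramp, and
   how reproducible is its formation across runs?

Because the underlying micrographs of the motivating study are not
deposited anywhere, the package ships seeded generators that emulate their
statistical structure, so every stage is exercised end-to-end with known
ground truth.

## The height-mixture model

Flattened AFM pixel heights $z$ from a field containing three surface
populations are modelled as a three-component Gaussian mixture,

$$ n(z) \propto \sum_{k \in \{\mathrm{mica},\,\mathrm{staple},\,\mathrm{origami}\}}
   P_k \frac{1}{\sigma_k} e^{-\frac{1}{2}\left(\frac{z-\mu_k}{\sigma_k}\right)^2},
   \qquad \sum_k P_k = 1 . $$

The nine parameters ($P_k$, $\mu_k$, $\sigma_k$) are estimated by fitting
the model's cumulative distribution function to the empirical CDF of
pixel heights by unweighted least squares:

$$ \hat\theta = \arg\min_\theta \sum_i
   \left[ F_{\mathrm{emp}}(z_i) - \sum_k P_k \,
   \Phi\!\left(\tfrac{z_i - \mu_k}{\sigma_k}\right) \right]^2 . $$

The staple-pixel fraction $P_\mathrm{staple}$ is the purity readout; the
fold change $P_\mathrm{staple}^{\mathrm{before}} /
P_\mathrm{staple}^{\mathrm{after}}$ summarises what purification removed.
A CDF-domain least-squares fit was chosen over likelihood/EM because the
CDF is the quantity the readout is defined on; no EM variant is offered.

### Numerical choices

* **Constraints.** The unit-sum constraint is enforced by optimising two
  softmax logits (the third fraction is the complement); positivity of the
  SDs by optimising $\log\sigma_k$. Optimisation is BFGS with an analytic
  gradient, 500 iterations max, relative tolerance $10^{-9}$.
* **Evaluation points.** The objective is evaluated at 8,000 uniformly
  subsampled (seeded) pixel heights by default (`max_points`). The induced
  sampling noise on a fraction is $\approx\sqrt{p(1-p)/8000} < 0.006$,
  an order of magnitude below the recovery tolerance we test; raising
  `max_points` to the full pixel count is supported when runtime does not
  matter. Maps under 100 pixels are refused outright, as are constant
  maps.
* **Initialisation.** The primary start comes from a kernel-density
  estimate of the heights (bandwidth widened 3×): the three modes carrying
  the most mass are kept, the heights are segmented at the density minima
  between them, and per-segment mass/mean/SD seed the optimiser. A fixed
  quantile start (means at the 25th/60th/95th percentiles, fractions
  0.6/0.3/0.1, common SD IQR/1.35/2) is the second restart, and further
  restarts jitter the KDE start. We found the fixed quantile start alone
  unreliable: when one population is rare it converges to a degenerate
  optimum that spends two components on the dominant mica bump. The KDE
  start adapts to arbitrary mass imbalance.
* **Label canonicalisation.** Components are sorted by mean height and
  labelled mica < staple < origami. Before labelling, components whose
  means differ by less than `merge_tol = 2` times the larger of their SDs
  are pooled (mass-weighted moments): such components describe a single
  pixel population, and the model CDF is invariant to how mass is split
  between them, so their individual labels would be arbitrary. This is
  what makes the single-population limit behave sensibly (a pure-mica map
  reports $P_\mathrm{mica} = 1$). Distinct populations take the lowest
  labels in height order; with fewer than three real populations the
  trailing labels carry zero mass. Set `merge_tol = 0` to disable.
* **Flattening.** An optional least-squares plane subtraction
  (`flatten = TRUE`) is offered for raw maps with scan bow; it is off by
  default because the generators produce already-flattened surfaces, and
  because preprocessing of real maps is better done in dedicated AFM
  software.

### Known limitations

Unweighted CDF least squares carries almost all of its statistical weight
where pixels are dense. A population holding less than about 1% of the
pixels contributes less to the objective than the empirical CDF's own
sampling fluctuations, so its fraction cannot be reliably resolved — a
degenerate re-use of its component elsewhere can even win the fit. The
recovery guarantees we test are therefore stated for fields in which each
population holds a few percent of pixels or more, with component means
separated by at least three of the largest SD. Heavily overlapping
populations (means closer than ~2 SD) are pooled by design, not resolved.

## Particle census

Nanotubes are detected by thresholding the height map and labelling
8-connected regions at or above `min_area_px` pixels. Two practical
details matter:

* **Pre-smoothing.** A 3×3 box mean (`smooth_px = 1`) precedes the
  threshold. Without it, per-pixel noise punches holes in tube interiors
  and fragments of one tube get counted as several particles; with it,
  isolated noise and small staple blobs are suppressed.
* **Threshold placement.** On the smoothed map the staple blobs sit near
  0.3 nm and tube interiors near 1.3 nm (with the default scene heights);
  we use 0.5 nm — roughly 2 SD above the staple level and 6 SD below the
  tube level. The asymmetry is deliberate: a staple exceedance creates a
  small region the area filter removes, while a tube dropout splits a
  particle in two, which no later step can repair (touching or
  overlapping tubes are *not* split either; there is no watershed step).

Contour length is measured by Zhang–Suen thinning of the region and
taking the longest path along the skeleton (orthogonal steps 1 px,
diagonal steps $\sqrt2$ px, two shortest-path sweeps — exact on the
tree-shaped skeletons thinning produces), scaled by the pixel size. An
axis-aligned thin rod of $n$ pixels measures exactly $(n-1)$ pixel
lengths; oblique tubes acquire a few percent of staircase inflation,
negligible against the ±50% classification windows.

Classification is by length alone, mirroring how monomers (~500 nm) and
dimers (~1000 nm) are told apart by eye: monomer in
$[250, 750)$ nm, dimer in $[750, 1500]$ nm, the 750 nm midpoint boundary
classifying as dimer (half-open convention), and everything else —
fragments, aggregates — as `other`. `other` particles are excluded from
the denominator of the reported monomer/dimer fractions. The predicted
design lengths use the B-DNA rise: $32 \times 42 \times 0.34 =
456.96$ nm for the monomer and $64\tfrac23 \times 42 \times 0.34 =
923.44$ nm for the dimer, presented at two significant figures (460 /
920 nm). The ~8 nm tube diameter is used only as a rendering default in
the generator, never asserted by the analysis.

## Half-subset bootstrap

The standard error of a binary content fraction over $N$ counted
particles is estimated by the study's resampling scheme: draw
$m = \mathrm{round}(N/2)$ elements *without replacement* (round half up,
so $N = 273 \Rightarrow m = 137$), record the subset mean, repeat 10,000
times, and report the SD (denominator $n-1$) of the subset means.
Because the draw is without replacement, this scheme has a closed form —
the SD of a hypergeometric mean,

$$ \mathrm{SE} = \sqrt{\frac{p(1-p)}{m}\,\frac{N-m}{N-1}} , $$

implemented as `analytic_half_subset_se()` and used as the independent
oracle in the tests (together with exhaustive subset enumeration for
$N \le 8$). Note what the oracle implies: at $N = 273$, $p = 57/273$ the
scheme's SE is ≈ 0.0246, and at $N = 114$, $p = 72/114$ it is ≈ 0.0456 —
reproducing the *procedure* does not reproduce every printed ±percentage
in the literature, which may fold in between-image variation. The
implementation follows the stated procedure.

## Gradient QC

Tube photographs reduce to depth–intensity profiles: per-row means over a
rectangular ROI, depth 0 at the top (meniscus), min–max normalised.
Profiles classify as

* `uniform` when the SD of the raw, un-normalised trace falls below
  `flatness_threshold` (default 0.05 on a unit-scaled image). The SD is
  used rather than the raw range because the range of a noisy flat trace
  grows with its length (~4.4 SD at 80 rows), which would misclassify any
  realistically noisy over-mixed tube; a unit ramp has SD ≈ 0.29 and a
  unit step 0.5, so the margin is wide.
* `step` when one single-point increment exceeds `step_score_threshold`
  (default 0.5) of the total rise — the signature of unmixed layers.
* `smooth` otherwise — the usable quasi-continuous gradient.

Reproducibility across replicate tubes is summarised as, per replicate,
the mean over depth of the absolute difference from the pointwise mean
profile, in percent of the normalised intensity range; the report gives
the mean and SD of those per-replicate deviations. The underlying
photographs of the motivating study are not available, and its printed
deviation statistic does not specify whether it averages over pixels,
depths or profiles; the definition above (per-profile mean over depth) is
fixed, documented, and what all tests assert. For $N$ replicates with
independent Gaussian intensity noise $\sigma$ the expected per-replicate
deviation is the folded-normal mean
$\sigma\sqrt{2/\pi}\sqrt{(N-1)/N}$ — with $\sigma = 0.05$ and $N = 20$,
about 3.9% — which the tests verify by simulation.

## What the generators emulate — and what they do not

`generate_afm_scene()` renders straight tubes of the designed width at
random orientations (placement rejects overlaps and keeps a 4 px
clearance so distinct tubes never touch, even after detection smoothing —
the dilute, sparsely distributed fields used for counting), staple
strands as ~5 px blobs scattered uniformly (origami takes priority where
they overlap), and pixel heights as class mean + Gaussian class deviate +
Gaussian instrument noise. That height model is *exactly* the mixture the
fit assumes. Default heights (mica 0, staples 0.5 nm, origami 2.0 nm, SDs
0.15/0.3/0.5 nm) are plausible stand-ins — the motivating study states no
height values, only that the three groups separate by intensity.

Deliberately not modelled: AFM tip convolution, scan-line artifacts, tube
curvature, aggregates and misfolds, dye optics or colour in tube photos,
and any sedimentation physics. Passing tests therefore demonstrate that
the *analysis chain* is correct and well-calibrated on data that match
its assumptions; they do not certify performance on real micrographs,
where preprocessing quality (flattening, deconvolution) dominates.

Counts are rounded half up everywhere a fractional count arises
(subset sizes, dimer counts), matching the resampling convention.

## Problem sizes used by the test-suite

The packaged checks run in minutes on one CPU by choice of problem size:
mixture-recovery fields are 224 × 224 px (~50k pixels, 20 seeds,
componentwise fraction error < 0.03 demanded), census fields
600 × 600 px with 8 tubes across dimer fractions {0, ¼, ½, ¾, 1} × 10
seeds (error < 0.05 demanded), bootstrap grids use 4,000–10,000
resamples, and gradient suites 20 replicates of 101 points. All
generators accept larger sizes.
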
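# Density-gradient quality control: profile extraction from tube photos,
# shape classification (step / smooth / uniform), and the cross-replicate
# absolute-deviation reproducibility statistic.

#' Extract a depth-intensity profile from a tube image
#'
#' Averages intensity per row over a rectangular region of interest, maps
#' rows to depth in \[0, 1\] (top of the ROI = 0 = meniscus), and min-max
#' normalizes. A constant ROI cannot be normalized and is returned
#' unchanged with `normalized = FALSE`.
#'
#' @param image numeric matrix, grayscale intensities (any scale; 8-bit
#'   images should be given on \[0, 1\] or \[0, 255\] consistently across
#'   replicates).
#' @param roi region of interest `c(row0, col0, height, width)` in pixels;
#'   default: the whole image.
#' @return a [gradient_profile()]; its `raw_range` attribute records the
#'   intensity range before normalization (used by [classify_profile()]).
#' @export
extract_profile <- function(image, roi = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(roi)) roi <- c(1L, 1L, nrow(image), ncol(image))
  if (length(roi) != 4L) stop("`roi` must be c(row0, col0, height, width)", call. = FALSE)
  r0 <- roi[1L]; c0 <- roi[2L]; h <- roi[3L]; w <- roi[4L]
  if (r0 < 1L || c0 < 1L || h < 1L || w < 1L ||
      r0 + h - 1L > nrow(image) || c0 + w - 1L > ncol(image)) {
    stop("`roi` must lie within the image with width/height >= 1", call. = FALSE)
  }
  sub <- image[r0:(r0 + h - 1L), c0:(c0 + w - 1L), drop = FALSE]
  trace <- rowMeans(sub)
  depth <- if (h > 1L) (seq_len(h) - 1) / (h - 1) else 0
  rng <- diff(range(trace))
  raw_sd <- if (h > 1L) stats::sd(trace) else 0
  if (rng == 0) {
    gradient_profile(depth, trace, normalized = FALSE, raw_range = 0,
                     raw_sd = raw_sd)
  } else {
    gradient_profile(depth, (trace - min(trace)) / rng,
                     normalized = TRUE, raw_range = rng, raw_sd = raw_sd)
  }
}

#' Classify a gradient profile's shape
#'
#' Decides between the three outcomes a tube can show: `uniform` (fully
#' mixed solution: the SD of the raw, un-normalized trace is below
#' `flatness_threshold`), `step` (essentially unmixed layers: one
#' single-point increment carries more than `step_score_threshold` of the
#' total rise), and `smooth` (a usable quasi-continuous gradient)
#' otherwise. The SD is used as the flatness evidence rather than the raw
#' range because the range of a noisy flat trace grows with its length.
#'
#' @param p a [gradient_profile()] with at least 4 points.
#' @param step_score_threshold fraction of the total rise that a single
#'   increment must exceed to call a step; default 0.5.
#' @param flatness_threshold raw-SD cut below which the tube is called
#'   uniform; default 0.05 (5% of a unit-scaled image; a unit ramp has
#'   SD ~ 0.29, a unit step 0.5).
#' @return one of `"step"`, `"smooth"`, `"uniform"`.
#' @export
classify_profile <- function(p, step_score_threshold = 0.5,
                             flatness_threshold = 0.05) {
  if (!inherits(p, "gradient_profile")) {
    stop("`p` must be a gradient_profile", call. = FALSE)
  }
  if (nrow(p) < 4L) stop("profile must have at least 4 points", call. = FALSE)
  raw_sd <- attr(p, "raw_sd")
  if (is.null(raw_sd)) raw_sd <- stats::sd(p$intensity)
  if (raw_sd < flatness_threshold) return("uniform")
  rise <- diff(range(p$intensity))
  if (rise == 0) return("uniform")
  if (max(abs(diff(p$intensity))) > step_score_threshold * rise) return("step")
  "smooth"
}

#' Cross-replicate reproducibility of gradient profiles
#'
#' Computes the pointwise mean profile and, for each replicate, the mean
#' over depth of the absolute difference from that mean profile, expressed
#' in percent of the normalized intensity range. Profiles on different
#' depth grids are resampled to the first profile's grid by linear
#' interpolation.
#'
#' @param profiles list of at least 2 [gradient_profile()] objects.
#' @return an object of class `repro_report`: list with
#'   `per_replicate_mad` (%), `mean_mad`, `sd_mad` (SD, ddof = 1), and
#'   `n_replicates`.
#' @examples
#' profs <- generate_gradient_replicates(20, "linear", noise_sd = 0.05,
#'                                       seed = 3)
#' mean_absolute_deviation(profs)$mean_mad  # about 4%
#' @export
mean_absolute_deviation <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L) {
    stop("need at least 2 profiles", call. = FALSE)
  }
  if (!all(vapply(profiles, inherits, TRUE, "gradient_profile"))) {
    stop("all elements must be gradient_profile objects", call. = FALSE)
  }
  grid <- profiles[[1L]]$depth
  mat <- vapply(profiles, function(p) {
    if (length(p$depth) == length(grid) && all(p$depth == grid)) {
      p$intensity
    } else {
      stats::approx(p$depth, p$intensity, xout = grid, rule = 2)$y
    }
  }, numeric(length(grid)))
  mean_profile <- rowMeans(mat)
  mads <- colMeans(abs(mat - mean_profile)) * 100
  structure(
    list(per_replicate_mad = unname(mads),
         mean_mad = mean(mads),
         sd_mad = stats::sd(mads),
         n_replicates = length(profiles)),
    class = "repro_report"
  )
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf(
    "<repro_report> absolute deviation from the mean: %.1f +/- %.1f%% (mean +/- SD, N = %d)\n",
    x$mean_mad, x$sd_mad, x$n_replicates))
  invisible(x)
}

#' Render a gradient profile as a synthetic tube photograph
#'
#' Inverse of [extract_profile()]: produces a grayscale image whose rows
#' follow the profile's intensity (plus optional pixel noise), for
#' round-trip testing of the extraction step. Labelled synthetic: no
#' camera, lighting or dye optics are modelled.
#'
#' @param p a [gradient_profile()].
#' @param width_px image width.
#' @param pixel_noise_sd SD of additive Gaussian pixel noise.
#' @param seed integer seed.
#' @return numeric matrix with `length(p$depth)` rows.
#' @export
render_profile_image <- function(p, width_px = 40L, pixel_noise_sd = 0,
                                 seed = 1L) {
  if (!inherits(p, "gradient_profile")) {
    stop("`p` must be a gradient_profile", call. = FALSE)
  }
  assert_count(width_px, "width_px", min = 1L)
  base <- matrix(rep(p$intensity, width_px), ncol = width_px)
  if (pixel_noise_sd > 0) {
    base <- base + with_seed(seed, {
      matrix(stats::rnorm(length(base), 0, pixel_noise_sd), nrow(base))
    })
  }
  base
}
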
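#' Specification of a synthetic AFM scene
#'
#' Describes a flattened AFM field of view containing three pixel
#' populations: the near-flat mica background, small staple-strand blobs,
#' and rod-shaped six-helix-bundle (6-hb) nanotubes (monomers and dimers).
#' Pixel heights are drawn as class mean + Gaussian class deviate + Gaussian
#' instrument noise, which is exactly the three-Gaussian model the mixture
#' decomposition assumes.
#'
#' Default heights (mica 0 nm, staples 0.5 nm, origami 2.0 nm with SDs
#' 0.15/0.3/0.5 nm) are plausible values for oligonucleotides and 6-hb
#' tubes on mica; real instruments vary, and only the ordering and
#' separability of the three populations matter to the analysis.
#'
#' @param width_px,height_px image size in pixels.
#' @param nm_per_pixel physical pixel size (nm).
#' @param mica_mu,staple_mu,origami_mu mean heights (nm); must be strictly
#'   increasing.
#' @param mica_sigma,staple_sigma,origami_sigma height SDs (nm), > 0.
#' @param n_monomers,n_dimers,n_staples object counts, >= 0.
#' @param monomer_len_nm,dimer_len_nm nominal tube contour lengths (nm);
#'   monomer < dimer. Defaults are the predicted 6-hb lengths (460/920 nm).
#' @param tube_width_nm rendered tube width (nm); default 8 nm, the
#'   approximate 6-hb diameter.
#' @param length_cv coefficient of variation of drawn tube lengths.
#' @param noise_sigma additive per-pixel instrument noise SD (nm), > 0.
#' @param seed integer seed; the same spec (including seed) always produces
#'   bit-identical output.
#' @return an object of class `scene_spec`.
#' @seealso [generate_afm_scene()]
#' @export
scene_spec <- function(width_px = 512L, height_px = 512L, nm_per_pixel = 4,
                       mica_mu = 0, staple_mu = 0.5, origami_mu = 2.0,
                       mica_sigma = 0.15, staple_sigma = 0.3,
                       origami_sigma = 0.5,
                       n_monomers = 5L, n_dimers = 2L, n_staples = 500L,
                       monomer_len_nm = 460, dimer_len_nm = 920,
                       tube_width_nm = 8, length_cv = 0.02,
                       noise_sigma = 0.1, seed = 1L) {
  spec <- list(
    width_px = assert_count(width_px, "width_px", min = 1L),
    height_px = assert_count(height_px, "height_px", min = 1L),
    nm_per_pixel = assert_scalar_number(nm_per_pixel, "nm_per_pixel", 0, TRUE),
    mica_mu = assert_scalar_number(mica_mu, "mica_mu"),
    staple_mu = assert_scalar_number(staple_mu, "staple_mu"),
    origami_mu = assert_scalar_number(origami_mu, "origami_mu"),
    mica_sigma = assert_scalar_number(mica_sigma, "mica_sigma", 0, TRUE),
    staple_sigma = assert_scalar_number(staple_sigma, "staple_sigma", 0, TRUE),
    origami_sigma = assert_scalar_number(origami_sigma, "origami_sigma", 0, TRUE),
    n_monomers = assert_count(n_monomers, "n_monomers"),
    n_dimers = assert_count(n_dimers, "n_dimers"),
    n_staples = assert_count(n_staples, "n_staples"),
    monomer_len_nm = assert_scalar_number(monomer_len_nm, "monomer_len_nm", 0, TRUE),
    dimer_len_nm = assert_scalar_number(dimer_len_nm, "dimer_len_nm", 0, TRUE),
    tube_width_nm = assert_scalar_number(tube_width_nm, "tube_width_nm", 0, TRUE),
    length_cv = assert_scalar_number(length_cv, "length_cv", 0),
    noise_sigma = assert_scalar_number(noise_sigma, "noise_sigma", 0, TRUE),
    seed = assert_count(abs(as.integer(seed)), "seed")
  )
  if (!(spec$mica_mu < spec$staple_mu && spec$staple_mu < spec$origami_mu)) {
    stop("component heights must satisfy mica_mu < staple_mu < origami_mu",
         call. = FALSE)
  }
  if (!(spec$monomer_len_nm < spec$dimer_len_nm)) {
    stop("monomer_len_nm must be < dimer_len_nm", call. = FALSE)
  }
  structure(spec, class = "scene_spec")
}

# Pixel set of a straight rod: centre (r0, c0) px, angle theta, length and
# width in px. Returns matrix indices of pixels whose centre lies within
# `halfwidth` of the centreline segment.
rod_pixels <- function(r0, c0, theta, length_px, halfwidth_px, nr, nc) {
  dx <- cos(theta); dy <- sin(theta)
  half <- length_px / 2
  pad <- halfwidth_px + 1
  rmin <- max(1L, floor(r0 - abs(dy) * half - pad))
  rmax <- min(nr, ceiling(r0 + abs(dy) * half + pad))
  cmin <- max(1L, floor(c0 - abs(dx) * half - pad))
  cmax <- min(nc, ceiling(c0 + abs(dx) * half + pad))
  if (rmin > rmax || cmin > cmax) {
    return(cbind(row = integer(0), col = integer(0)))
  }
  rows <- rmin:rmax; cols <- cmin:cmax
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  # signed coordinates relative to the centre, projected on the rod axis
  px <- cc - c0; py <- rr - r0
  t <- px * dx + py * dy
  t_clamped <- pmax(-half, pmin(half, t))
  d2 <- (px - t_clamped * dx)^2 + (py - t_clamped * dy)^2
  keep <- d2 <= halfwidth_px^2
  cbind(row = rr[keep], col = cc[keep])
}

#' Generate a synthetic AFM scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: dimer and monomer
#' nanotubes are placed as straight, randomly oriented rods of width
#' `tube_width_nm` (placement rejects overlaps between tubes and keeps a
#' small margin so distinct tubes never touch); staples are small blobs
#' scattered uniformly, allowed to overlap tubes (overlapping pixels keep
#' the higher class: origami over staple over mica). Every pixel's height is
#' its class mean plus a Gaussian deviate of the class SD plus Gaussian
#' instrument noise.
#'
#' @param spec a [scene_spec()].
#' @param max_attempts placement attempts per tube before giving up with an
#'   error (the scene is then too crowded for the requested tubes).
#' @return a list with elements
#'   \describe{
#'     \item{map}{a [height_map()];}
#'     \item{truth}{a `ground_truth` list: `class_map` (integer matrix,
#'       0 = mica, 1 = staple, 2 = origami), `particles` (tibble of centroid
#'       row/col, true length nm, true class), and `pixel_fractions`
#'       (named numeric, sums to 1 exactly).}
#'   }
#' @examples
#' sc <- generate_afm_scene(scene_spec(width_px = 128, height_px = 128,
#'                                     n_monomers = 1, n_dimers = 0,
#'                                     n_staples = 40, seed = 7))
#' sc$truth$pixel_fractions
#' @export
generate_afm_scene <- function(spec, max_attempts = 200L) {
  if (!inherits(spec, "scene_spec")) {
    stop("`spec` must be a scene_spec", call. = FALSE)
  }
  nr <- spec$height_px; nc <- spec$width_px
  npp <- spec$nm_per_pixel
  with_seed(spec$seed, {
    class_map <- matrix(0L, nr, nc)  # 0 mica, 1 staple, 2 origami
    halfwidth_px <- (spec$tube_width_nm / 2) / npp
    # clearance so distinct tubes stay separate even after a 3x3 detection
    # smoothing (emulates the sparse deposition used for AFM counting)
    margin_px <- halfwidth_px + 4

    n_tubes <- spec$n_dimers + spec$n_monomers
    true_class <- rep(c("dimer", "monomer"),
                      c(spec$n_dimers, spec$n_monomers))
    mean_len <- ifelse(true_class == "dimer",
                       spec$dimer_len_nm, spec$monomer_len_nm)
    lengths_nm <- mean_len * (1 + spec$length_cv * stats::rnorm(n_tubes))
    lengths_nm <- pmax(lengths_nm, npp)  # degenerate guard

    particles <- vector("list", n_tubes)
    for (i in seq_len(n_tubes)) {
      len_px <- lengths_nm[i] / npp
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        theta <- stats::runif(1, 0, pi)
        half_r <- abs(sin(theta)) * len_px / 2 + halfwidth_px + 1
        half_c <- abs(cos(theta)) * len_px / 2 + halfwidth_px + 1
        if (2 * half_r + 2 > nr || 2 * half_c + 2 > nc) next
        r0 <- stats::runif(1, 1 + half_r, nr - half_r)
        c0 <- stats::runif(1, 1 + half_c, nc - half_c)
        guard <- rod_pixels(r0, c0, theta, len_px, margin_px, nr, nc)
        if (any(class_map[guard] == 2L)) next
        core <- rod_pixels(r0, c0, theta, len_px, halfwidth_px, nr, nc)
        class_map[core] <- 2L
        particles[[i]] <- tibble::tibble(
          centroid_row = mean(core[, "row"]), centroid_col = mean(core[, "col"]),
          length_nm = lengths_nm[i], class = true_class[i]
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "could not place tube %d (%s, %.0f nm) after %d attempts; scene too small or crowded",
          i, true_class[i], lengths_nm[i], max_attempts
        ), call. = FALSE)
      }
    }

    if (spec$n_staples > 0L) {
      # each staple is a small plus-shaped blob (~5 px at 4 nm/px)
      sr <- sample.int(nr, spec$n_staples, replace = TRUE)
      sc <- sample.int(nc, spec$n_staples, replace = TRUE)
      off <- rbind(c(0L, 0L), c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
      rr <- rep(sr, each = nrow(off)) + off[, 1L]
      cc <- rep(sc, each = nrow(off)) + off[, 2L]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      idx <- cbind(rr[ok], cc[ok])
      keep <- class_map[idx] == 0L   # origami keeps priority
      class_map[idx[keep, , drop = FALSE]] <- 1L
    }

    mu <- c(spec$mica_mu, spec$staple_mu, spec$origami_mu)[class_map + 1L]
    sg <- c(spec$mica_sigma, spec$staple_sigma, spec$origami_sigma)[class_map + 1L]
    z <- mu + sg * stats::rnorm(length(class_map)) +
      spec$noise_sigma * stats::rnorm(length(class_map))
    z <- matrix(z, nr, nc)

    counts <- tabulate(class_map + 1L, nbins = 3L)
    fr <- counts / length(class_map)
    fr[3L] <- 1 - fr[1L] - fr[2L]    # force exact unit sum
    names(fr) <- c("mica", "staple", "origami")

    truth <- structure(
      list(
        class_map = class_map,
        particles = if (n_tubes > 0L) do.call(rbind, particles) else
          tibble::tibble(centroid_row = numeric(0), centroid_col = numeric(0),
                         length_nm = numeric(0), class = character(0)),
        pixel_fractions = fr
      ),
      class = "ground_truth"
    )
    list(map = height_map(z, npp), truth = truth)
  })
}

#' Generate a labelled sample of particle lengths
#'
#' Emulates a manually counted AFM field: exactly `round(n * dimer_fraction)`
#' particles (round half up) are dimers, the rest monomers, in seeded random
#' order. Lengths are Gaussian around the class mean with SD
#' `length_cv * mean`, truncated to be positive.
#'
#' @param n sample size, >= 1.
#' @param dimer_fraction fraction of dimers in \[0, 1\].
#' @param monomer_len_nm,dimer_len_nm class mean lengths (nm).
#' @param length_cv coefficient of variation of lengths, >= 0.
#' @param seed integer seed.
#' @return a tibble with columns `length_nm` and `label`
#'   (`"monomer"`/`"dimer"`).
#' @examples
#' s <- generate_length_sample(273, 0.21, seed = 1)
#' table(s$label)   # 57 dimers: round(273 * 0.21)
#' @export
generate_length_sample <- function(n, dimer_fraction,
                                   monomer_len_nm = 460, dimer_len_nm = 920,
                                   length_cv = 0.05, seed = 1L) {
  assert_count(n, "n", min = 1L)
  assert_scalar_number(dimer_fraction, "dimer_fraction", min = 0)
  if (dimer_fraction > 1) stop("`dimer_fraction` must be in [0, 1]", call. = FALSE)
  assert_scalar_number(length_cv, "length_cv", min = 0)
  n_dimer <- round_half_up(n * dimer_fraction)
  with_seed(seed, {
    label <- sample(rep(c("dimer", "monomer"), c(n_dimer, n - n_dimer)))
    mean_len <- ifelse(label == "dimer", dimer_len_nm, monomer_len_nm)
    len <- mean_len * (1 + length_cv * stats::rnorm(n))
    while (any(len <= 0)) {  # truncation at > 0; essentially never at small cv
      bad <- len <= 0
      len[bad] <- mean_len[bad] * (1 + length_cv * stats::rnorm(sum(bad)))
    }
    tibble::tibble(length_nm = len, label = label)
  })
}

#' A depth-intensity gradient profile
#'
#' @param depth ascending depths in \[0, 1\] (0 = meniscus / tube top).
#' @param intensity intensity trace, same length as `depth`.
#' @param normalized whether `intensity` has been min-max normalized.
#' @param raw_range intensity range before normalization, on the source
#'   scale.
#' @param raw_sd intensity SD before normalization, on the source scale
#'   (used by [classify_profile()] to recognise uniform tubes; unlike the
#'   range it does not grow with profile length under noise).
#' @return a tibble of class `gradient_profile` with attributes
#'   `normalized`, `raw_range` and `raw_sd`.
#' @export
gradient_profile <- function(depth, intensity, normalized = TRUE,
                             raw_range = diff(range(intensity)),
                             raw_sd = stats::sd(intensity)) {
  if (length(depth) != length(intensity)) {
    stop("`depth` and `intensity` must have the same length", call. = FALSE)
  }
  if (is.unsorted(depth, strictly = TRUE)) {
    stop("`depth` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(depth = depth, intensity = intensity)
  class(out) <- c("gradient_profile", class(out))
  attr(out, "normalized") <- normalized
  attr(out, "raw_range") <- raw_range
  attr(out, "raw_sd") <- raw_sd
  out
}

gradient_shapes <- c("step", "linear", "sigmoid", "uniform")

# noiseless base curves on a unit depth grid, all spanning [0,1] except uniform
gradient_base_curve <- function(shape, depth) {
  switch(shape,
    step = as.numeric(depth >= 0.5),
    linear = depth,
    sigmoid = {
      raw <- stats::plogis((depth - 0.5) * 12)
      (raw - min(raw)) / (max(raw) - min(raw))
    },
    uniform = rep(0.5, length(depth)),
    stop(sprintf("unknown gradient shape '%s' (use one of %s)", shape,
                 paste(gradient_shapes, collapse = ", ")), call. = FALSE)
  )
}

#' Generate replicate gradient profiles
#'
#' Emulates densitometry traces of gradient tubes: a noiseless base curve
#' per shape — `step` (jump at depth 0.5), `linear` (unit ramp), `sigmoid`
#' (logistic ramp), `uniform` (constant) — plus additive Gaussian noise on
#' the normalized intensity.
#'
#' @param n_replicates number of replicate tubes, >= 1.
#' @param shape one of `"step"`, `"linear"`, `"sigmoid"`, `"uniform"`.
#' @param n_points samples per profile over depth \[0, 1\], >= 2.
#' @param noise_sd SD of additive Gaussian intensity noise, >= 0.
#' @param seed integer seed.
#' @return a list of [gradient_profile()] objects.
#' @examples
#' profs <- generate_gradient_replicates(3, "linear", n_points = 11,
#'                                       noise_sd = 0, seed = 1)
#' profs[[1]]$intensity[6]  # 0.5 at mid-depth of a unit ramp
#' @export
generate_gradient_replicates <- function(n_replicates, shape = "step",
                                         n_points = 101L, noise_sd = 0,
                                         seed = 1L) {
  assert_count(n_replicates, "n_replicates", min = 1L)
  assert_count(n_points, "n_points", min = 2L)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  shape <- match.arg(shape, gradient_shapes)
  depth <- seq(0, 1, length.out = n_points)
  base <- gradient_base_curve(shape, depth)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      intensity <- base + noise_sd * stats::rnorm(n_points)
      gradient_profile(depth, intensity,
                       normalized = shape != "uniform",
                       raw_range = diff(range(intensity)))
    })
  })
}

#' Write gradient profiles to CSV
#'
#' Long format with columns `depth,intensity,replicate`.
#'
#' @param profiles list of [gradient_profile()] objects.
#' @param path output CSV path.
#' @export
write_gradient_profiles <- function(profiles, path) {
  rows <- lapply(seq_along(profiles), function(i) {
    tibble::tibble(depth = profiles[[i]]$depth,
                   intensity = profiles[[i]]$intensity,
                   replicate = i)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
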
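# Particle detection, contour-length measurement and the monomer/dimer
# census. Detection replaces the manual counting step: nanotubes sit well
# above the mica background, so a height threshold plus 8-connected
# component labeling isolates them.

# 8-connected component labeling of a logical matrix via the pixel
# adjacency graph. Returns a list of pixel-index matrices (row, col).
label_components_8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  fgidx <- which(fg)
  if (length(fgidx) == 0L) return(list())
  lookup <- integer(nr * nc)
  lookup[fgidx] <- seq_along(fgidx)
  edges <- list()
  # undirected 8-neighbourhood covered by E, S, SE, SW offsets
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    both <- fg & shift_mat(fg, -o[1L], -o[2L], fill = FALSE)
    from <- which(both)
    if (length(from)) {
      to <- from + o[1L] + o[2L] * nr
      edges[[length(edges) + 1L]] <- rbind(lookup[from], lookup[to])
    }
  }
  g <- igraph::make_graph(edges = if (length(edges)) as.vector(do.call(cbind, edges)) else integer(0),
                          n = length(fgidx), directed = FALSE)
  memb <- igraph::components(g)$membership
  rows <- ((fgidx - 1L) %% nr) + 1L
  cols <- ((fgidx - 1L) %/% nr) + 1L
  lapply(split(seq_along(fgidx), memb), function(i) {
    cbind(row = rows[i], col = cols[i])
  })
}

#' Detect particles in a height map
#'
#' Thresholds the map at `height_threshold_nm` (which must sit above the
#' mica background) and labels 8-connected regions of at least
#' `min_area_px` pixels. Regions are returned in deterministic order by
#' centroid (row, then column).
#'
#' @param map a [height_map()].
#' @param height_threshold_nm height cut (nm) separating particles from
#'   background.
#' @param min_area_px minimum region area in pixels, >= 1.
#' @param smooth_px half-width of a box mean filter applied before
#'   thresholding (0 disables). Smoothing bridges single-pixel dropouts
#'   inside tall particles and suppresses isolated noise pixels; the
#'   default of 1 (a 3x3 mean) is appropriate for tubes a few pixels
#'   wide.
#' @return a list of `particle` objects: each a list with `pixels`
#'   (matrix of row/col indices), `centroid` (row, col), `area_px`.
#' @export
detect_particles <- function(map, height_threshold_nm, min_area_px = 5L,
                             smooth_px = 1L) {
  validate_height_map(map)
  assert_scalar_number(height_threshold_nm, "height_threshold_nm")
  assert_count(min_area_px, "min_area_px", min = 1L)
  assert_count(smooth_px, "smooth_px", min = 0L)
  z <- if (smooth_px > 0L) box_smooth(map$heights, smooth_px) else map$heights
  comps <- label_components_8(z > height_threshold_nm)
  comps <- Filter(function(px) nrow(px) >= min_area_px, comps)
  particles <- lapply(comps, function(px) {
    structure(
      list(pixels = px,
           centroid = c(row = mean(px[, "row"]), col = mean(px[, "col"])),
           area_px = nrow(px)),
      class = "particle"
    )
  })
  ord <- order(vapply(particles, function(p) p$centroid["row"], 0),
               vapply(particles, function(p) p$centroid["col"], 0))
  particles[ord]
}

# (2k+1)^2 box mean filter with edge-replication, via cumulative sums.
box_smooth <- function(z, k) {
  nr <- nrow(z); nc <- ncol(z)
  zp <- z[pmin(pmax(seq(1L - k, nr + k), 1L), nr),
          pmin(pmax(seq(1L - k, nc + k), 1L), nc)]
  cs <- apply(apply(zp, 2L, cumsum), 1L, cumsum)  # transposed cumsum matrix
  cs <- rbind(0, cbind(0, t(cs)))
  w <- 2L * k + 1L
  (cs[(1L + w):(nr + w), (1L + w):(nc + w)] -
     cs[1:nr, (1L + w):(nc + w)] -
     cs[(1L + w):(nr + w), 1:nc] + cs[1:nr, 1:nc]) / (w * w)
}

# Zhang-Suen thinning of a logical matrix (TRUE = foreground).
thin_zhang_suen <- function(img) {
  img <- img * 1L
  # neighbour order P2..P9 = N, NE, E, SE, S, SW, W, NW (row down = south)
  offs <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  neigh <- function(m) {
    lapply(offs, function(o) shift_mat(m, -o[1L], -o[2L], fill = 0L))
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- neigh(img)
      b <- Reduce(`+`, p)
      ring <- c(p, p[1L])
      a <- Reduce(`+`, lapply(1:8, function(i) {
        (ring[[i]] == 0L) * (ring[[i + 1L]] == 1L)
      }))
      if (step == 1L) {
        c1 <- p[[1L]] * p[[3L]] * p[[5L]] == 0L  # P2*P4*P6
        c2 <- p[[3L]] * p[[5L]] * p[[7L]] == 0L  # P4*P6*P8
      } else {
        c1 <- p[[1L]] * p[[3L]] * p[[7L]] == 0L  # P2*P4*P8
        c2 <- p[[1L]] * p[[5L]] * p[[7L]] == 0L  # P2*P6*P8
      }
      del <- img == 1L & b >= 2L & b <= 6L & a == 1L & c1 & c2
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

#' Measure a particle's contour length
#'
#' Skeletonizes the particle region (Zhang-Suen thinning) and returns the
#' length of the longest path along the skeleton, with orthogonal steps
#' counting 1 pixel and diagonal steps `sqrt(2)` pixels, times the pixel
#' size. The longest path is found by two shortest-path sweeps on the
#' weighted skeleton graph (exact on tree-shaped skeletons, which is what
#' thinning a rod produces).
#'
#' @param p a `particle` from [detect_particles()].
#' @param nm_per_pixel physical pixel size (nm).
#' @return contour length in nm; a single-pixel particle returns 0 with a
#'   warning.
#' @export
measure_contour_length <- function(p, nm_per_pixel) {
  if (!inherits(p, "particle")) stop("`p` must be a particle", call. = FALSE)
  assert_scalar_number(nm_per_pixel, "nm_per_pixel", 0, TRUE)
  px <- p$pixels
  if (nrow(px) == 0L) stop("particle has no pixels", call. = FALSE)
  if (nrow(px) == 1L) {
    warning("single-pixel particle; contour length reported as 0")
    return(0)
  }
  # crop to a padded bounding box
  r0 <- min(px[, "row"]) - 1L; c0 <- min(px[, "col"]) - 1L
  nr <- max(px[, "row"]) - r0 + 1L
  nc <- max(px[, "col"]) - c0 + 1L
  m <- matrix(FALSE, nr + 1L, nc + 1L)
  m[cbind(px[, "row"] - r0, px[, "col"] - c0)] <- TRUE
  skel <- thin_zhang_suen(m)
  sk_idx <- which(skel)
  if (length(sk_idx) <= 1L) return(0)

  snr <- nrow(skel)
  lookup <- integer(length(skel))
  lookup[sk_idx] <- seq_along(sk_idx)
  edges <- NULL; weights <- NULL
  offs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))
  for (o in offs) {
    both <- skel & shift_mat(skel, -o[1L], -o[2L], fill = FALSE)
    from <- which(both)
    if (length(from)) {
      to <- from + o[1L] + o[2L] * snr
      edges <- cbind(edges, rbind(lookup[from], lookup[to]))
      weights <- c(weights, rep(o[3L], length(from)))
    }
  }
  if (is.null(edges)) return(0)
  g <- igraph::make_graph(edges = as.vector(edges), n = length(sk_idx),
                          directed = FALSE)
  igraph::E(g)$weight <- weights
  d1 <- igraph::distances(g, v = 1L)
  d1[!is.finite(d1)] <- -1
  far <- which.max(d1)
  d2 <- igraph::distances(g, v = far)
  d2[!is.finite(d2)] <- -1
  max(d2) * nm_per_pixel
}

#' Classify a particle by contour length
#'
#' Monomers and dimers are told apart by length alone: a particle counts as
#' a monomer in `[monomer_ref * (1 - window), boundary)` and as a dimer in
#' `[boundary, dimer_ref * (1 + window)]`, where the boundary is the
#' midpoint of the two references (750 nm by default, itself classified as
#' dimer); anything else — fragments, aggregates — is `"other"`.
#'
#' @param length_nm particle length(s) in nm, >= 0.
#' @param monomer_ref_nm,dimer_ref_nm reference lengths (nm), monomer <
#'   dimer; defaults 500/1000 nm, the apparent monomer/dimer lengths.
#' @param window acceptance half-width as a fraction of each reference,
#'   in (0, 0.5\].
#' @return character vector of labels in `{"monomer", "dimer", "other"}`.
#' @examples
#' classify_by_length(c(500, 1000, 750, 120))
#' @export
classify_by_length <- function(length_nm, monomer_ref_nm = 500,
                               dimer_ref_nm = 1000, window = 0.5) {
  if (any(!is.finite(length_nm)) || any(length_nm < 0)) {
    stop("lengths must be finite and >= 0", call. = FALSE)
  }
  assert_scalar_number(monomer_ref_nm, "monomer_ref_nm", 0, TRUE)
  assert_scalar_number(dimer_ref_nm, "dimer_ref_nm", 0, TRUE)
  if (monomer_ref_nm >= dimer_ref_nm) {
    stop("monomer_ref_nm must be < dimer_ref_nm", call. = FALSE)
  }
  if (window <= 0 || window > 0.5) {
    stop("`window` must be in (0, 0.5]", call. = FALSE)
  }
  boundary <- (monomer_ref_nm + dimer_ref_nm) / 2
  out <- rep("other", length(length_nm))
  out[length_nm >= monomer_ref_nm * (1 - window) & length_nm < boundary] <- "monomer"
  out[length_nm >= boundary & length_nm <= dimer_ref_nm * (1 + window)] <- "dimer"
  out
}

#' Tabulate a monomer/dimer census
#'
#' Counts labels and reports monomer/dimer fractions over the
#' monomer + dimer subset only; `"other"` particles are excluded from the
#' denominator. With no monomers or dimers the fractions are `NA`.
#'
#' @param labels character vector of labels (`"monomer"`, `"dimer"`,
#'   `"other"`), e.g. from [classify_by_length()].
#' @return an object of class `census`: list with counts `n_monomer`,
#'   `n_dimer`, `n_other` and `monomer_fraction`, `dimer_fraction`.
#' @examples
#' census(c("monomer", "monomer", "dimer"))$dimer_fraction  # 1/3
#' @export
census <- function(labels) {
  if (length(labels) && !all(labels %in% c("monomer", "dimer", "other"))) {
    stop("labels must be 'monomer', 'dimer' or 'other'", call. = FALSE)
  }
  n_m <- sum(labels == "monomer")
  n_d <- sum(labels == "dimer")
  n_o <- sum(labels == "other")
  denom <- n_m + n_d
  structure(
    list(n_monomer = n_m, n_dimer = n_d, n_other = n_o,
         monomer_fraction = if (denom > 0) n_m / denom else NA_real_,
         dimer_fraction = if (denom > 0) n_d / denom else NA_real_),
    class = "census"
  )
}

#' @export
print.census <- function(x, ...) {
  cat(sprintf("<census> %d monomer, %d dimer, %d other; dimer content %s\n",
              x$n_monomer, x$n_dimer, x$n_other,
              if (is.na(x$dimer_fraction)) "undefined"
              else sprintf("%.1f%%", 100 * x$dimer_fraction)))
  invisible(x)
}

#' Full census of a height map
#'
#' Convenience pipeline: detect particles, measure contour lengths,
#' classify by length, tabulate. Returns both the per-particle table and
#' the aggregate census.
#'
#' @inheritParams detect_particles
#' @inheritParams classify_by_length
#' @return list with `particles` (tibble: particle_id, centroid_row,
#'   centroid_col, area_px, length_nm, label) and `census` ([census()]).
#' @export
census_height_map <- function(map, height_threshold_nm, min_area_px = 5L,
                              monomer_ref_nm = 500, dimer_ref_nm = 1000,
                              window = 0.5, smooth_px = 1L) {
  parts <- detect_particles(map, height_threshold_nm, min_area_px, smooth_px)
  lens <- vapply(parts, measure_contour_length, 0,
                 nm_per_pixel = map$nm_per_pixel)
  labels <- if (length(lens)) {
    classify_by_length(lens, monomer_ref_nm, dimer_ref_nm, window)
  } else {
    character(0)
  }
  tab <- tibble::tibble(
    particle_id = seq_along(parts),
    centroid_row = vapply(parts, function(p) unname(p$centroid["row"]), 0),
    centroid_col = vapply(parts, function(p) unname(p$centroid["col"]), 0),
    area_px = vapply(parts, function(p) p$area_px, 0L),
    length_nm = as.numeric(lens),
    label = labels
  )
  list(particles = tab, census = census(labels))
}

#' Predicted contour length of a multi-segment DNA origami
#'
#' A 6-helix-bundle design of `n_segments` segments of `bp_per_segment`
#' base pairs each has predicted contour length
#' `n_segments * bp_per_segment * nm_per_bp` at the B-DNA rise of
#' 0.34 nm per base pair. Exact arithmetic; use [present_length_nm()] to
#' round to the two significant figures customarily quoted.
#'
#' @param n_segments number of segments (may be fractional, e.g. a 2/3
#'   connector segment).
#' @param bp_per_segment base pairs per segment.
#' @param nm_per_bp helix rise per base pair (nm); default 0.34.
#' @return length in nm.
#' @examples
#' predict_contour_length(32, 42)          # 456.96
#' present_length_nm(predict_contour_length(32, 42))       # 460
#' present_length_nm(predict_contour_length(64 + 2/3, 42)) # 920
#' @export
predict_contour_length <- function(n_segments, bp_per_segment, nm_per_bp = 0.34) {
  assert_scalar_number(n_segments, "n_segments", min = 0)
  assert_scalar_number(bp_per_segment, "bp_per_segment", min = 0)
  assert_scalar_number(nm_per_bp, "nm_per_bp", min = 0)
  n_segments * bp_per_segment * nm_per_bp
}
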
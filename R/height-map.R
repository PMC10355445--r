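#' Calibrated AFM height map
#'
#' A `height_map` is a numeric matrix of surface heights in nanometres plus
#' the physical pixel size. It is the raw input to both the mixture
#' decomposition ([fit_height_mixture()]) and the particle census
#' ([detect_particles()]). Rows are scan lines (top to bottom), columns are
#' pixels along a line.
#'
#' @param heights numeric matrix of heights (nm); all values must be finite.
#' @param nm_per_pixel physical size of one pixel (nm), > 0.
#' @return an object of class `height_map`.
#' @examples
#' hm <- height_map(matrix(rnorm(400), 20), nm_per_pixel = 4)
#' dim(hm$heights)
#' @export
height_map <- function(heights, nm_per_pixel) {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    stop("`heights` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(heights))) {
    stop("all heights must be finite", call. = FALSE)
  }
  assert_scalar_number(nm_per_pixel, "nm_per_pixel", min = 0, strict_min = TRUE)
  structure(
    list(heights = heights, nm_per_pixel = nm_per_pixel),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "<height_map> %d x %d px at %.3g nm/px (%.3g x %.3g nm), heights %.3g..%.3g nm\n",
    nrow(x$heights), ncol(x$heights), x$nm_per_pixel,
    nrow(x$heights) * x$nm_per_pixel, ncol(x$heights) * x$nm_per_pixel,
    min(x$heights), max(x$heights)
  ))
  invisible(x)
}

is_height_map <- function(x) inherits(x, "height_map")

validate_height_map <- function(map, min_pixels = 1L) {
  if (!is_height_map(map)) stop("expected a `height_map` object", call. = FALSE)
  if (length(map$heights) < min_pixels) {
    stop(sprintf(
      "height map has %d pixels; at least %d are required",
      length(map$heights), min_pixels
    ), call. = FALSE)
  }
  invisible(map)
}

#' Write / read a height map as 32-bit float TIFF with a JSON sidecar
#'
#' Heights are linearly rescaled to \[0, 1\] for storage (the float-TIFF
#' writer requires that range); the sidecar `<path>.json` records `z_min`,
#' `z_max` and `nm_per_pixel` so the map is reconstructed in physical units.
#' A constant map is stored with `z_max = z_min` and read back as constant.
#'
#' @param map a [height_map()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `write_height_map()` returns `path` invisibly; `read_height_map()`
#'   returns a [height_map()].
#' @export
write_height_map <- function(map, path) {
  validate_height_map(map)
  z <- map$heights
  z_min <- min(z); z_max <- max(z)
  scaled <- if (z_max > z_min) (z - z_min) / (z_max - z_min) else z * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(z_min = z_min, z_max = z_max, nm_per_pixel = map$nm_per_pixel,
         units = "nm"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing sidecar ", sidecar, " (written by write_height_map)",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  scaled <- tiff::readTIFF(path)
  if (length(dim(scaled)) == 3L) scaled <- scaled[, , 1L]
  z <- scaled * (as.numeric(meta$z_max) - as.numeric(meta$z_min)) +
    as.numeric(meta$z_min)
  height_map(z, as.numeric(meta$nm_per_pixel))
}

#' Write / read a height map as a plain-text matrix
#'
#' Tab-separated heights in nm with a two-line header carrying the pixel
#' size. Exact (full double precision) and human-inspectable; preferred for
#' small fixtures.
#'
#' @inheritParams write_height_map
#' @export
write_height_map_txt <- function(map, path) {
  validate_height_map(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# height_map nm", sprintf("# nm_per_pixel %.17g", map$nm_per_pixel)), con)
  utils::write.table(format(map$heights, digits = 17, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_height_map_txt
#' @export
read_height_map_txt <- function(path) {
  header <- readLines(path, n = 2L)
  npp <- as.numeric(sub("^# nm_per_pixel ", "", header[2L]))
  z <- as.matrix(utils::read.table(path, skip = 2L, sep = "\t"))
  dimnames(z) <- NULL
  height_map(z, npp)
}
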
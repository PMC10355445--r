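# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going up (0.5 -> 1), the convention
#' used for subset sizes and label counts throughout the package. Base R's
#' `round()` rounds half to even, which would give 136 for 136.5.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never disturb the
# session RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage label, deterministically
# and below 2^31, so pipeline stages get independent but reproducible streams.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single non-negative integer", name), call. = FALSE)
  }
  if (x < min) stop(sprintf("`%s` must be >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Shift a matrix by (dr, dc), padding with `fill`. Used by the thinning and
# adjacency code; vectorised replacement for explicit pixel loops.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Present a length to two significant figures
#'
#' Contour-length predictions are reported at two significant figures
#' (456.96 nm -> 460 nm), matching how predicted nanostructure lengths are
#' conventionally quoted.
#'
#' @param length_nm numeric length(s) in nm.
#' @return numeric vector rounded to 2 significant figures.
#' @export
present_length_nm <- function(length_nm) {
  signif(length_nm, 2)
}
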
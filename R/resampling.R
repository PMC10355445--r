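# Half-subset bootstrap for the standard error of a binary content
# fraction. The scheme: from N binary observations, repeatedly draw
# round(N/2) elements WITHOUT replacement, record the subset mean, and
# report the SD of those means as the standard error. Because the draw is
# without replacement, the scheme has a closed-form answer (the SD of a
# hypergeometric mean), implemented here as an independent oracle.

#' Half-subset bootstrap SE of a binary fraction
#'
#' @param values binary vector (0/1), e.g. monomer = 0, dimer = 1; length
#'   >= 2.
#' @param n_resamples number of subsets drawn (default 10,000).
#' @param seed integer seed.
#' @return an object of class `bootstrap_result`: list with
#'   `point_estimate` (mean of `values`), `se` (SD, ddof = 1, of the subset
#'   means), `n`, `subset_size` (`round(n/2)`, half up), `n_resamples`,
#'   `seed`.
#' @examples
#' x <- c(rep(1, 57), rep(0, 216))  # 21% dimer content, N = 273
#' half_subset_se(x, seed = 1)$se   # about 0.0246
#' @export
half_subset_se <- function(values, n_resamples = 10000L, seed = 1L) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (!is.numeric(values) || !all(values %in% c(0, 1))) {
    stop("`values` must be binary (0/1); encode monomer = 0, dimer = 1",
         call. = FALSE)
  }
  assert_count(n_resamples, "n_resamples", min = 1L)
  n <- length(values)
  m <- round_half_up(n / 2)
  means <- with_seed(seed, {
    vapply(seq_len(n_resamples),
           function(i) mean(values[sample.int(n, m)]), 0)
  })
  structure(
    list(point_estimate = mean(values), se = stats::sd(means),
         n = n, subset_size = m, n_resamples = as.integer(n_resamples),
         seed = as.integer(seed)),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> fraction %.4f +/- %.4f (SE; n = %d, subsets of %d x %d, seed %d)\n",
    x$point_estimate, x$se, x$n, x$subset_size, x$n_resamples, x$seed))
  invisible(x)
}

#' Closed-form SE of the half-subset scheme
#'
#' The mean of a without-replacement draw of size `m = round(n/2)` from `n`
#' binary items with success fraction `p` is a scaled hypergeometric; its
#' SD is `sqrt(p * (1 - p) / m * (n - m) / (n - 1))`. This is the exact
#' value the Monte-Carlo SE of [half_subset_se()] converges to, and serves
#' as its independent oracle.
#'
#' @param p success fraction in \[0, 1\]; `n * p` must be an integer (a
#'   realisable composition).
#' @param n population size, >= 2.
#' @return the exact SE.
#' @examples
#' analytic_half_subset_se(0.5, 100)  # 0.050252...
#' @export
analytic_half_subset_se <- function(p, n) {
  assert_scalar_number(p, "p", min = 0)
  if (p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  assert_count(n, "n", min = 2L)
  if (abs(n * p - round(n * p)) > 1e-8) {
    stop("`n * p` must be an integer (whole number of successes)", call. = FALSE)
  }
  m <- round_half_up(n / 2)
  sqrt(p * (1 - p) / m * (n - m) / (n - 1))
}
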
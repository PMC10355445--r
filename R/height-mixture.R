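#' Parameters of the three-Gaussian pixel-height mixture
#'
#' The pixel-height distribution of an AFM field is modelled as a mixture of
#' three normal components — mica background, staple strands, origami
#' nanostructures — with mixing fractions `p_*` (summing to 1), mean heights
#' `mu_*` (nm) and SDs `sigma_*` (nm). Components are kept in canonical
#' order `mu_mica <= mu_staple <= mu_origami`.
#'
#' @param p_mica,p_staple,p_origami mixing fractions in \[0, 1\], summing to
#'   1 within 1e-9.
#' @param mu_mica,mu_staple,mu_origami component mean heights (nm),
#'   non-decreasing.
#' @param sigma_mica,sigma_staple,sigma_origami component SDs (nm), > 0.
#' @return an object of class `mixture_params`.
#' @export
mixture_params <- function(p_mica, p_staple, p_origami,
                           mu_mica, mu_staple, mu_origami,
                           sigma_mica, sigma_staple, sigma_origami) {
  p <- c(p_mica, p_staple, p_origami)
  mu <- c(mu_mica, mu_staple, mu_origami)
  sigma <- c(sigma_mica, sigma_staple, sigma_origami)
  if (any(!is.finite(c(p, mu, sigma)))) {
    stop("all mixture parameters must be finite", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("fractions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (is.unsorted(mu)) {
    stop("means must satisfy mu_mica <= mu_staple <= mu_origami", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("all sigmas must be > 0", call. = FALSE)
  structure(
    list(p = stats::setNames(p, c("mica", "staple", "origami")),
         mu = stats::setNames(mu, c("mica", "staple", "origami")),
         sigma = stats::setNames(sigma, c("mica", "staple", "origami"))),
    class = "mixture_params"
  )
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("<mixture_params>\n")
  print(round(rbind(p = x$p, mu_nm = x$mu, sigma_nm = x$sigma), 4))
  invisible(x)
}

#' Empirical CDF of pixel heights
#'
#' Sorts the pixel heights and assigns `F(z_i) = i / n`; tied heights
#' collapse to the highest rank, so `F` is a proper step CDF ending at 1.
#' Maps larger than `max_points` pixels are uniformly subsampled (seeded)
#' before sorting, which bounds the cost of the mixture fit without
#' changing the distribution.
#'
#' @param map a [height_map()] with at least 100 pixels.
#' @param max_points subsampling cap (default 50,000).
#' @param seed seed for the subsample draw.
#' @return an object of class `empirical_cdf`: list with ascending
#'   `z_sorted` (nm) and cumulative fractions `F` in (0, 1\].
#' @examples
#' hm <- height_map(matrix(rnorm(400), 20), 4)
#' ec <- empirical_cdf(hm)
#' utils::tail(ec$F, 1)  # 1
#' @export
empirical_cdf <- function(map, max_points = 50000L, seed = 1L) {
  validate_height_map(map, min_pixels = 100L)
  z <- as.vector(map$heights)
  if (length(z) > max_points) {
    z <- with_seed(seed, z[sample.int(length(z), max_points)])
  }
  z <- sort(z)
  n <- length(z)
  f <- seq_len(n) / n
  keep <- c(z[-1L] != z[-n], TRUE)   # ties collapse to the highest rank
  structure(list(z_sorted = z[keep], F = f[keep], n = n),
            class = "empirical_cdf")
}

#' Mixture model CDF
#'
#' Evaluates the cumulative distribution function of the three-Gaussian
#' height mixture, `sum_k p_k * Phi((z - mu_k) / sigma_k)`. Monotone
#' non-decreasing in `z`, tending to 0 and 1 at the tails.
#'
#' @param params a [mixture_params()].
#' @param z height(s) in nm.
#' @return model CDF value(s) in \[0, 1\].
#' @examples
#' th <- mixture_params(1, 0, 0, 0, 0, 0, 1, 1, 1)
#' model_cdf(th, 0)  # 0.5
#' @export
model_cdf <- function(params, z) {
  if (!inherits(params, "mixture_params")) {
    stop("`params` must be a mixture_params", call. = FALSE)
  }
  out <- numeric(length(z))
  for (k in 1:3) {
    out <- out + params$p[k] * stats::pnorm(z, params$mu[k], params$sigma[k])
  }
  unname(out)
}

# --- internals of the CDF least-squares fit ---------------------------------

# theta = (l1, l2, mu1, mu2, mu3, log s1, log s2, log s3);
# p = softmax(l1, l2, 0) so the unit-sum constraint is built in.
theta_to_params_raw <- function(theta) {
  l <- c(theta[1:2], 0)
  e <- exp(l - max(l))
  list(p = e / sum(e), mu = theta[3:5], sigma = exp(theta[6:8]))
}

# optim calls the objective and gradient separately at the same theta, so
# the value/gradient pair is computed once and memoised on the last theta.
make_mixfit_fns <- function(z, f_emp) {
  cache_theta <- NULL
  cache <- NULL
  compute <- function(theta) {
    if (!is.null(cache_theta) && identical(theta, cache_theta)) return(cache)
    pr <- theta_to_params_raw(theta)
    phi_k <- matrix(0, length(z), 3)  # component CDFs
    den_k <- matrix(0, length(z), 3)  # standardised densities
    u_k <- matrix(0, length(z), 3)
    for (k in 1:3) {
      u <- (z - pr$mu[k]) / pr$sigma[k]
      u_k[, k] <- u
      phi_k[, k] <- stats::pnorm(u)
      den_k[, k] <- stats::dnorm(u)
    }
    m <- as.vector(phi_k %*% pr$p)
    r <- m - f_emp
    r2 <- 2 * r
    g <- numeric(8)
    for (j in 1:2) {  # softmax logits: d m / d l_j = p_j (Phi_j - m)
      g[j] <- sum(r2 * pr$p[j] * (phi_k[, j] - m))
    }
    for (k in 1:3) {  # means: d Phi_k / d mu_k = -phi(u)/sigma
      g[2 + k] <- sum(r2 * pr$p[k] * (-den_k[, k] / pr$sigma[k]))
    }
    for (k in 1:3) {  # log sigmas: d Phi_k / d log sigma = -phi(u) * u
      g[5 + k] <- sum(r2 * pr$p[k] * (-den_k[, k] * u_k[, k]))
    }
    cache_theta <<- theta
    cache <<- list(value = sum(r * r), gradient = g)
    cache
  }
  list(fn = function(theta) compute(theta)$value,
       gr = function(theta) compute(theta)$gradient)
}

params_to_theta <- function(p, mu, sigma) {
  p <- pmax(p, 1e-6); p <- p / sum(p)
  c(log(p[1] / p[3]), log(p[2] / p[3]), mu, log(sigma))
}

# Moment-based starting point from a smoothed kernel density estimate:
# take the three modes carrying the most mass, cut at the density minima
# between them, and use per-segment mass/mean/SD. Handles very unbalanced
# components (a sub-1% origami mode) that fixed quantile starts miss.
# Returns NULL when fewer than three modes are resolved.
kde_valley_init <- function(z, adjust = 3) {
  d <- stats::density(z, n = 512L, adjust = adjust)
  y <- d$y; x <- d$x
  sgn <- diff(sign(diff(y)))
  maxs <- which(sgn == -2) + 1L
  if (length(maxs) < 3L) return(NULL)
  bounds <- c(1L, which(sgn == 2) + 1L, length(y))
  mass <- vapply(maxs, function(i) {
    lo <- max(bounds[bounds <= i]); hi <- min(bounds[bounds >= i])
    sum(y[lo:hi])
  }, 0)
  top <- sort(maxs[order(mass, decreasing = TRUE)[1:3]])
  cut1 <- x[top[1L] + which.min(y[top[1L]:top[2L]]) - 1L]
  cut2 <- x[top[2L] + which.min(y[top[2L]:top[3L]]) - 1L]
  seg <- findInterval(z, c(cut1, cut2)) + 1L
  if (length(unique(seg)) < 3L) return(NULL)
  p <- tabulate(seg, 3L) / length(z)
  mu <- as.numeric(tapply(z, seg, mean))
  s <- as.numeric(tapply(z, seg, stats::sd))
  params_to_theta(p, mu, pmax(ifelse(is.na(s), 1e-3, s), 1e-3))
}

# Canonicalise an optimiser solution: sort components by mu, merge
# effectively coincident components, and force exact unit sum.
#
# When two fitted components have nearly the same mean relative to their
# SDs they describe a single pixel population and the split of mass
# between them is arbitrary (the model CDF is unchanged under any split),
# so the sorted-by-mu labels would be meaningless. Components with
# |delta mu| <= merge_tol * max(sigma) are therefore pooled
# (mass-weighted mean and variance); the distinct populations then take
# the lowest labels in height order and trailing labels carry zero mass.
canonical_params <- function(p, mu, sigma, merge_tol = 2) {
  ord <- order(mu)
  p <- p[ord]; mu <- mu[ord]; sigma <- sigma[ord]
  if (merge_tol > 0) {
    repeat {
      if (length(p) == 1L) break
      gaps <- diff(mu) / pmax(sigma[-length(sigma)], sigma[-1L])
      i <- which.min(gaps)
      if (gaps[i] > merge_tol) break
      w <- p[i] + p[i + 1L]
      wi <- if (w > 0) p[i] / w else 0.5
      m <- wi * mu[i] + (1 - wi) * mu[i + 1L]
      v <- wi * (sigma[i]^2 + mu[i]^2) + (1 - wi) * (sigma[i + 1L]^2 + mu[i + 1L]^2) - m^2
      p <- c(p[seq_len(i - 1L)], w, p[-seq_len(i + 1L)])
      mu <- c(mu[seq_len(i - 1L)], m, mu[-seq_len(i + 1L)])
      sigma <- c(sigma[seq_len(i - 1L)], sqrt(max(v, 1e-12)), sigma[-seq_len(i + 1L)])
    }
  }
  while (length(p) < 3L) {  # pad with zero-mass copies of the top component
    p <- c(p, 0)
    mu <- c(mu, mu[length(mu)])
    sigma <- c(sigma, sigma[length(sigma)])
  }
  p <- pmin(pmax(p / sum(p), 0), 1)
  p <- p / sum(p)
  p[3] <- max(1 - p[1] - p[2], 0)
  mixture_params(p[1], p[2], p[3], mu[1], mu[2], mu[3],
                 sigma[1], sigma[2], sigma[3])
}

#' Fit the three-Gaussian mixture CDF to a height map
#'
#' Minimises the unweighted sum of squared differences between the
#' empirical CDF of pixel heights and the mixture model CDF over the nine
#' parameters, with the unit-sum constraint on the fractions enforced by a
#' softmax parameterisation and positivity of the SDs by log-transform.
#' Components of the returned fit are sorted by mean height, so `p_staple`
#' of the fit is the reported staple-pixel fraction.
#'
#' Initialisation places the means at the 25th/60th/95th height percentiles
#' with fractions (0.6, 0.3, 0.1) and a common SD of `(IQR / 1.35) / 2`;
#' the remaining `n_restarts - 1` starts are seeded jitters of that point,
#' and the best final objective wins.
#'
#' @param map a [height_map()] (>= 100 pixels, non-constant).
#' @param init optional [mixture_params()] used as the first start.
#' @param n_restarts number of optimiser starts, >= 1.
#' @param seed seed for subsampling and restart jitter.
#' @param max_points number of (seeded, uniformly subsampled) pixel heights
#'   the least-squares objective is evaluated at. The default of 8,000
#'   keeps the fit fast; the induced sampling noise on the fractions is
#'   about `sqrt(p (1 - p) / max_points)`, under 0.006. Raise it (up to
#'   the full pixel count) for final estimates if desired.
#' @param flatten if `TRUE`, subtract the least-squares plane from the map
#'   first (simple scan-bow removal); default off.
#' @param merge_tol components of the optimum whose means differ by less
#'   than `merge_tol` times the larger of their SDs are pooled before
#'   labeling (they describe one pixel population and the split of mass
#'   between them is arbitrary); the distinct populations then take the
#'   lowest labels in height order. Set to 0 to disable.
#' @return an object of class `mixture_fit`: list with `params`
#'   ([mixture_params()]), `objective` (sum of squared CDF residuals),
#'   `n_pixels`, `converged`, `n_restarts_used`.
#' @export
fit_height_mixture <- function(map, init = NULL, n_restarts = 5L, seed = 1L,
                               max_points = 8000L, flatten = FALSE,
                               merge_tol = 2) {
  validate_height_map(map, min_pixels = 100L)
  if (isTRUE(flatten)) map <- flatten_plane(map)
  z_all <- as.vector(map$heights)
  if (diff(range(z_all)) == 0) {
    stop("height map is constant; the mixture fit is undefined", call. = FALSE)
  }
  assert_count(n_restarts, "n_restarts", min = 1L)
  ec <- empirical_cdf(map, max_points = max_points, seed = seed)
  z <- ec$z_sorted; f_emp <- ec$F

  q <- stats::quantile(z, c(0.25, 0.60, 0.95), names = FALSE)
  iqr <- stats::IQR(z)
  s0 <- max((iqr / 1.35) / 2, 1e-3)
  theta0 <- if (is.null(init)) {
    params_to_theta(c(0.6, 0.3, 0.1), q, rep(s0, 3))
  } else {
    if (!inherits(init, "mixture_params")) {
      stop("`init` must be a mixture_params", call. = FALSE)
    }
    params_to_theta(init$p, init$mu, init$sigma)
  }

  spread <- diff(range(z))
  starts <- with_seed(seed, {
    # KDE valley start first (robust even when one component is rare),
    # the quantile start second, then seeded jitters of the KDE start.
    theta_kde <- kde_valley_init(z)
    if (is.null(theta_kde)) theta_kde <- theta0
    lapply(seq_len(n_restarts), function(i) {
      if (i == 1L) return(theta_kde)
      if (i == 2L) return(theta0)
      theta_kde + c(stats::rnorm(2, 0, 0.5), stats::rnorm(3, 0, 0.05 * spread),
                    stats::rnorm(3, 0, 0.3))
    })
  })

  fns <- make_mixfit_fns(z, f_emp)
  best <- NULL
  n_conv <- 0L
  for (th in starts) {
    res <- tryCatch(
      stats::optim(th, fns$fn, fns$gr, method = "BFGS",
                   control = list(maxit = 500L, reltol = 1e-9)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all optimiser starts failed", call. = FALSE)
  }
  pr <- theta_to_params_raw(best$par)
  structure(
    list(
      params = canonical_params(pr$p, pr$mu, pr$sigma, merge_tol),
      objective = best$value,
      n_pixels = length(z_all),
      n_fit_points = ec$n,
      converged = n_conv > 0L && best$convergence == 0L,
      n_restarts_used = n_restarts
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d px (%d fit points), SSE %.4g, %s\n",
              x$n_pixels, x$n_fit_points, x$objective,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

# least-squares plane subtraction (optional pre-step; AFM scan bow removal)
flatten_plane <- function(map) {
  z <- map$heights
  nr <- nrow(z); nc <- ncol(z)
  r <- rep(seq_len(nr), times = nc); c_ <- rep(seq_len(nc), each = nr)
  fit <- stats::lm.fit(cbind(1, r, c_), as.vector(z))
  height_map(matrix(fit$residuals, nr, nc), map$nm_per_pixel)
}

#' Staple-fraction fold reduction between two fields
#'
#' The purification figure of merit: the ratio of the staple pixel fraction
#' before purification to after. A value of 2.14, say, means purification
#' removed more than half of the staple-associated pixels.
#'
#' @param fit_before,fit_after converged [fit_height_mixture()] results for
#'   the unpurified and purified field; bare numeric staple fractions are
#'   also accepted (e.g. literature values).
#' @return the fold change `p_staple(before) / p_staple(after)`.
#' @examples
#' staple_reduction(0.62, 0.29)  # 2.138
#' @export
staple_reduction <- function(fit_before, fit_after) {
  p_before <- extract_p_staple(fit_before, "fit_before")
  p_after <- extract_p_staple(fit_after, "fit_after")
  if (p_after < 1e-9) {
    stop("p_staple after purification is zero or near zero; fold change undefined",
         call. = FALSE)
  }
  unname(p_before / p_after)
}

extract_p_staple <- function(x, name) {
  if (inherits(x, "mixture_fit")) {
    if (!isTRUE(x$converged)) {
      stop(sprintf("`%s` did not converge; refusing to report a fold change", name),
           call. = FALSE)
    }
    return(unname(x$params$p["staple"]))
  }
  if (is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1) {
    return(x)
  }
  stop(sprintf("`%s` must be a mixture_fit or a staple fraction in [0, 1]", name),
       call. = FALSE)
}

#' Write a mixture fit to JSON
#'
#' All nine parameters plus diagnostics, machine-readable.
#'
#' @param fit a `mixture_fit`.
#' @param path output path.
#' @export
write_mixture_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mixture_fit"))
  jsonlite::write_json(
    list(
      p_mica = unname(fit$params$p[1]), p_staple = unname(fit$params$p[2]),
      p_origami = unname(fit$params$p[3]),
      mu_mica = unname(fit$params$mu[1]), mu_staple = unname(fit$params$mu[2]),
      mu_origami = unname(fit$params$mu[3]),
      sigma_mica = unname(fit$params$sigma[1]),
      sigma_staple = unname(fit$params$sigma[2]),
      sigma_origami = unname(fit$params$sigma[3]),
      objective = fit$objective, n_pixels = fit$n_pixels,
      converged = fit$converged, n_restarts_used = fit$n_restarts_used
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
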
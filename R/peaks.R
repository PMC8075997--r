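# Ks peak location: Gaussian-kernel density of block median Ks values,
# then nonlinear least-squares fitting of a sum of Gaussians to the
# smoothed curve, adding components until the coefficient of
# determination reaches the acceptance threshold.

#' Gaussian kernel density of Ks values
#'
#' Kernel-smoothed probability density of (block median) Ks values on an
#' even grid over [0, max + 4 * bandwidth]. The bandwidth is the standard
#' deviation of the Gaussian kernel.
#'
#' @param ks_values Numeric vector (length >= 5) of Ks values.
#' @param bandwidth Kernel standard deviation in Ks units (default
#'   0.025).
#' @param n_grid Number of grid points (default 512).
#' @return Object of class \code{kde_curve}: list with \code{grid},
#'   \code{density}, \code{bandwidth}.
#' @export
ks_kde <- function(ks_values, bandwidth = 0.025, n_grid = 512) {
  ks_values <- ks_values[!is.na(ks_values)]
  if (length(ks_values) < 5) {
    stop("need at least 5 Ks values for a density estimate, got ",
         length(ks_values))
  }
  stopifnot(bandwidth > 0)
  d <- stats::density(ks_values, bw = bandwidth, kernel = "gaussian",
                      from = 0, to = max(ks_values) + 4 * bandwidth,
                      n = n_grid)
  structure(list(grid = d$x, density = d$y, bandwidth = bandwidth),
            class = "kde_curve")
}

# trapezoid integral of a kde_curve
curve_mass <- function(curve) {
  sum(diff(curve$grid) * (utils::head(curve$density, -1) +
                            utils::tail(curve$density, -1)) / 2)
}

# Local maxima of y ranked by topographic prominence (height above the
# highest saddle separating the peak from any higher peak).
peak_candidates <- function(x, y) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) is_max <- c(1L, is_max)
  if (y[n] > y[n - 1]) is_max <- c(is_max, n)
  if (length(is_max) == 0) is_max <- which.max(y)
  prom <- vapply(is_max, function(i) {
    higher <- is_max[y[is_max] > y[i]]
    if (length(higher) == 0) return(y[i])
    saddle <- max(vapply(higher, function(h) {
      rng <- if (h < i) h:i else i:h
      min(y[rng])
    }, numeric(1)))
    y[i] - saddle
  }, numeric(1))
  ord <- order(-prom, x[is_max])  # ties: leftmost first
  data.frame(x = x[is_max][ord], y = y[is_max][ord], prominence = prom[ord])
}

mixture_value <- function(x, comps) {
  y <- rep(0, length(x))
  for (i in seq_len(nrow(comps))) {
    y <- y + comps$weight[i] *
      stats::dnorm(x, comps$mu[i], comps$sigma[i])
  }
  y
}

r_squared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

fit_k_components <- function(x, y, start, bandwidth) {
  k <- nrow(start)
  par0 <- c(start$weight, start$mu, start$sigma)
  names(par0) <- c(paste0("w", 1:k), paste0("m", 1:k), paste0("s", 1:k))
  form <- stats::as.formula(paste(
    "y ~ ", paste(sprintf("w%d * dnorm(x, m%d, s%d)", 1:k, 1:k, 1:k),
                  collapse = " + ")))
  lower <- c(rep(0, k), rep(min(x), k), rep(bandwidth / 4, k))
  upper <- c(rep(Inf, k), rep(max(x), k), rep(max(x) - min(x), k))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(x = x, y = y),
                      start = as.list(par0), lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    comps <- start
  } else {
    p <- stats::coef(fit)
    comps <- data.frame(weight = p[paste0("w", 1:k)],
                        mu = p[paste0("m", 1:k)],
                        sigma = p[paste0("s", 1:k)])
  }
  r2 <- r_squared(y, mixture_value(x, comps))
  # never return something worse than the starting point
  r2_start <- r_squared(y, mixture_value(x, start))
  if (r2_start > r2) {
    comps <- start
    r2 <- r2_start
  }
  list(components = comps, r_squared = r2)
}

#' Fit a Gaussian mixture to a Ks density curve
#'
#' Least-squares fit of a sum of Gaussian components to the smoothed
#' density, increasing the number of components from 1 until the
#' coefficient of determination reaches \code{r2_min} or
#' \code{max_components} is hit. Components are initialized from the
#' prominence-ranked local maxima of the curve (then of the fit
#' residuals) and returned sorted by mean.
#'
#' @param curve A \code{kde_curve}.
#' @param max_components Maximum number of Gaussian components
#'   (default 5).
#' @param r2_min Acceptance threshold for the coefficient of
#'   determination (default 0.95).
#' @return Object of class \code{mixture_fit}: \code{components}
#'   (data.frame mu, sigma, weight, sorted by mu), \code{r_squared},
#'   \code{accepted} (did the fit reach \code{r2_min}) and
#'   \code{n_components}.
#' @export
fit_mixture <- function(curve, max_components = 5, r2_min = 0.95) {
  stopifnot(inherits(curve, "kde_curve"), r2_min > 0, r2_min <= 1,
            max_components >= 1)
  x <- curve$grid
  y <- curve$density
  cand <- peak_candidates(x, y)
  mass <- curve_mass(curve)
  best <- NULL
  prev <- NULL
  for (k in seq_len(max_components)) {
    starts <- list()
    if (k <= nrow(cand)) {
      sig0 <- pmax(curve$bandwidth * 2, 0.02)
      starts$fresh <- data.frame(
        weight = pmax(cand$y[1:k], 1e-3) * sig0 * sqrt(2 * pi),
        mu = cand$x[1:k], sigma = sig0)
    }
    if (!is.null(prev)) {
      resid <- y - mixture_value(x, prev$components)
      at <- x[which.max(resid)]
      starts$incremental <- rbind(
        prev$components[, c("weight", "mu", "sigma")],
        data.frame(weight = max(max(resid), 1e-4) * 0.05,
                   mu = at, sigma = pmax(curve$bandwidth * 2, 0.02)))
    }
    fit_k <- NULL
    for (s in starts) {
      f <- fit_k_components(x, y, s, curve$bandwidth)
      if (is.null(fit_k) || f$r_squared > fit_k$r_squared) fit_k <- f
    }
    if (is.null(fit_k)) break
    prev <- fit_k
    if (is.null(best) || fit_k$r_squared > best$r_squared) {
      best <- fit_k
      best$n_components <- k
    }
    if (best$r_squared >= r2_min) break
  }
  comps <- best$components[order(best$components$mu),
                           c("mu", "sigma", "weight")]
  rownames(comps) <- NULL
  structure(
    list(components = comps, r_squared = best$r_squared,
         accepted = best$r_squared >= r2_min,
         n_components = nrow(comps), curve_mass = mass),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: %d component(s), R^2 = %.4f%s\n",
              x$n_components, x$r_squared,
              if (x$accepted) "" else " (below threshold)"))
  print(round(x$components, 4))
  invisible(x)
}
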
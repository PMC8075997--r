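# Evolutionary-rate correction of Ks peaks. Lineages differ in molecular
# clock rate r_i; each species gets a correction coefficient
# lambda_i = 1/r_i so that a between-genome peak mu_{i-j} rescales to
# lambda_i * lambda_j * mu_{i-j}. The coefficients are estimated from the
# shared basal divergences: a slowly evolving reference species ("slow"
# anchor, lambda fixed at 1) and a second basal anchor species both
# diverged from every ingroup species at the same time, so the ratio of
# their Ks peaks against a baseline species to their peaks against
# species i estimates a_i = lambda_i / lambda_baseline. The slowest
# ingroup species pins max{lambda_i} = 1, giving
# lambda_baseline = 1 / max{a_i}.

#' Build a peak table
#'
#' A peak table maps species comparisons ("i-j", including "i-i" for
#' within-genome paralog peaks) to the Gaussian component chosen as that
#' comparison's divergence peak.
#'
#' @param comparisons data.frame with columns species_i, species_j, mu
#'   and optionally sigma (NA when unknown).
#' @return Object of class \code{peak_table}: named list of
#'   \code{list(mu, sigma)} keyed by "i-j" (order as given).
#' @export
peak_table <- function(comparisons) {
  stopifnot(all(c("species_i", "species_j", "mu") %in%
                  names(comparisons)))
  if (is.null(comparisons$sigma)) comparisons$sigma <- NA_real_
  keys <- paste(comparisons$species_i, comparisons$species_j, sep = "-")
  if (anyDuplicated(keys)) stop("duplicate comparison keys")
  pt <- lapply(seq_len(nrow(comparisons)), function(i)
    list(mu = comparisons$mu[i], sigma = comparisons$sigma[i]))
  names(pt) <- keys
  structure(pt, class = "peak_table")
}

peak_lookup <- function(peaks, i, j) {
  p <- peaks[[paste(i, j, sep = "-")]]
  if (is.null(p)) p <- peaks[[paste(j, i, sep = "-")]]
  p
}

#' Select each comparison's divergence peak from mixture fits
#'
#' By default the component with the largest weight is taken as the
#' divergence peak of a between-genome comparison; individual
#' comparisons can be overridden by component index.
#'
#' @param fits Named list of \code{mixture_fit} objects, keyed "i-j".
#' @param component Optional named integer vector of overrides: which
#'   component (1-based, sorted by mu) to use for a given key.
#' @return A \code{peak_table}.
#' @export
peaks_from_fits <- function(fits, component = NULL) {
  rows <- lapply(names(fits), function(key) {
    comps <- fits[[key]]$components
    idx <- if (!is.null(component) && key %in% names(component)) {
      component[[key]]
    } else {
      which.max(comps$weight)
    }
    sp <- strsplit(key, "-", fixed = TRUE)[[1]]
    data.frame(species_i = sp[1], species_j = sp[2],
               mu = comps$mu[idx], sigma = comps$sigma[idx],
               stringsAsFactors = FALSE)
  })
  peak_table(do.call(rbind, rows))
}

#' Estimate the rate ratio a_i of one species
#'
#' \code{a_i = mean(mu[slow-baseline] / mu[slow-i],
#' mu[second-baseline] / mu[second-i])}: the mean ratio of the two basal
#' anchors' Ks peaks against the baseline species to their peaks against
#' species i. Returns exactly 1 for the baseline species itself.
#'
#' @param peaks A \code{peak_table}.
#' @param species Species to estimate.
#' @param anchors Named character vector with entries \code{slow} (the
#'   slowly evolving reference, lambda = 1), \code{second} (the second
#'   basal anchor) and \code{baseline} (the calibration species).
#' @return The ratio a_i (numeric scalar).
#' @export
estimate_a <- function(peaks, species,
                       anchors = c(slow = "At", second = "Ef",
                                   baseline = "Vv")) {
  stopifnot(inherits(peaks, "peak_table"),
            all(c("slow", "second", "baseline") %in% names(anchors)))
  if (species == anchors[["baseline"]]) return(1)
  need <- list(
    c(anchors[["slow"]], anchors[["baseline"]]),
    c(anchors[["slow"]], species),
    c(anchors[["second"]], anchors[["baseline"]]),
    c(anchors[["second"]], species))
  mus <- vapply(need, function(pr) {
    p <- peak_lookup(peaks, pr[1], pr[2])
    if (is.null(p)) {
      stop("missing anchor peak for comparison ", pr[1], "-", pr[2])
    }
    p$mu
  }, numeric(1))
  mean(c(mus[1] / mus[2], mus[3] / mus[4]))
}

#' Solve the per-species correction coefficients
#'
#' Given the a_i ratios, sets \code{lambda_baseline = 1 / max(a_i)} and
#' \code{lambda_i = lambda_baseline * a_i}; the slow anchor's lambda is
#' pinned at 1. By construction the maximum lambda over the corrected
#' species equals 1 (attained by the slowest species).
#'
#' @param a Named numeric vector of a_i ratios (must include the
#'   baseline species with value 1).
#' @param anchors As in \code{\link{estimate_a}}.
#' @return Object of class \code{rate_model}: list with \code{a},
#'   \code{lambda} (including the slow anchor at 1) and the implied
#'   rates \code{r = 1/lambda}.
#' @export
solve_lambda <- function(a, anchors = c(slow = "At", second = "Ef",
                                        baseline = "Vv")) {
  if (length(a) == 0) stop("empty a vector")
  if (any(a <= 0)) stop("nonpositive a ratio")
  lam_base <- 1 / max(a)
  lambda <- lam_base * a
  lambda[[anchors[["slow"]]]] <- 1
  structure(list(a = a, lambda = lambda, r = 1 / lambda,
                 anchors = anchors),
            class = "rate_model")
}

#' Rate model from a peak table
#'
#' Convenience wrapper: estimates a_i for every non-anchor species in
#' the table and solves the lambda system.
#'
#' @inheritParams estimate_a
#' @param species Character vector of species to correct; defaults to
#'   every species appearing in the table except the two basal anchors.
#' @return A \code{rate_model}.
#' @export
fit_rate_model <- function(peaks, species = NULL,
                           anchors = c(slow = "At", second = "Ef",
                                       baseline = "Vv")) {
  if (is.null(species)) {
    all_sp <- unique(unlist(strsplit(names(peaks), "-", fixed = TRUE)))
    species <- setdiff(all_sp, anchors[c("slow", "second")])
  }
  a <- vapply(species, estimate_a, numeric(1), peaks = peaks,
              anchors = anchors)
  solve_lambda(a, anchors)
}

#' Rate-correct a Ks peak
#'
#' Rescales a Gaussian Ks peak by \code{lambda_i * lambda_j}: the mean
#' and standard deviation both scale linearly (the variance by the
#' square). For a within-genome paralog peak use \code{li = lj}.
#'
#' @param peak List with \code{mu} and \code{sigma} (sigma may be NA).
#' @param li,lj Correction coefficients of the two species.
#' @return List with \code{mu_corrected}, \code{sigma_corrected}.
#' @export
correct_distribution <- function(peak, li, lj) {
  stopifnot(li > 0, lj > 0)
  list(mu_corrected = li * lj * peak$mu,
       sigma_corrected = li * lj * peak$sigma)
}

#' Calibration for Ks-to-age conversion
#'
#' @param mu_ref Corrected Ks peak of the reference event.
#' @param age_low,age_high Age interval of the reference event in Ma
#'   (defaults 115 and 130, the major-eudicot common hexaploidy).
#' @param label Reference event label.
#' @return Object of class \code{ks_calibration}.
#' @export
ks_calibration <- function(mu_ref, age_low = 115, age_high = 130,
                           label = "eudicot hexaploidy") {
  stopifnot(mu_ref > 0, age_low > 0, age_high > age_low)
  structure(list(label = label, mu_ref = mu_ref, age_low = age_low,
                 age_high = age_high),
            class = "ks_calibration")
}

#' Date an event from its corrected Ks peak
#'
#' Ages scale linearly with corrected Ks:
#' \code{age = mu_corrected / mu_ref * [age_low, age_high]}. Reported
#' endpoints are rounded to integer Ma; raw values are retained.
#'
#' @param event_peak List with \code{mu_corrected} (from
#'   \code{\link{correct_distribution}}) or a numeric scalar.
#' @param cal A \code{\link{ks_calibration}}.
#' @return List with \code{age_low}, \code{age_high} (integer Ma),
#'   \code{age_low_raw}, \code{age_high_raw}.
#' @export
date_event <- function(event_peak, cal) {
  stopifnot(inherits(cal, "ks_calibration"))
  mu <- if (is.list(event_peak)) event_peak$mu_corrected else event_peak
  if (!is.numeric(mu) || mu <= 0) stop("nonpositive event peak")
  lo <- mu / cal$mu_ref * cal$age_low
  hi <- mu / cal$mu_ref * cal$age_high
  list(age_low = round(lo), age_high = round(hi),
       age_low_raw = lo, age_high_raw = hi)
}

#' Check corrected-peak consistency of a rate model
#'
#' After correction, every anchor-versus-ingroup peak should equal the
#' corresponding anchor-versus-baseline peak. Reports the maximum
#' relative deviation over all such checks.
#'
#' @inheritParams estimate_a
#' @param model A \code{rate_model} solved from the same peaks.
#' @return List with \code{deviations} (named numeric) and
#'   \code{max_deviation}.
#' @export
consistency_check <- function(peaks, model,
                              anchors = c(slow = "At", second = "Ef",
                                          baseline = "Vv")) {
  stopifnot(inherits(model, "rate_model"))
  lam <- model$lambda
  base <- anchors[["baseline"]]
  devs <- numeric(0)
  for (anchor in anchors[c("slow", "second")]) {
    ref <- peak_lookup(peaks, anchor, base)
    if (is.null(ref)) next
    la <- if (anchor %in% names(lam)) lam[[anchor]] else 1
    ref_c <- la * lam[[base]] * ref$mu
    for (sp in setdiff(names(model$a), base)) {
      p <- peak_lookup(peaks, anchor, sp)
      if (is.null(p)) next
      cor_mu <- la * lam[[sp]] * p$mu
      devs[[paste(anchor, sp, sep = "-")]] <- abs(cor_mu / ref_c - 1)
    }
  }
  list(deviations = devs,
       max_deviation = if (length(devs)) max(devs) else 0)
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Rate model (anchors:",
      paste(names(x$anchors), x$anchors, sep = "=", collapse = ", "),
      ")\n")
  print(round(rbind(a = x$a[names(x$a)],
                    lambda = x$lambda[names(x$a)]), 4))
  invisible(x)
}
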
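# Continuous-curve representation of per-subject time series and uniform
# resampling. Curves are cubic splines with knots at the observed times:
# exact interpolation (Forsythe-Malcolm-Moler end conditions, which reproduce
# global cubics) or GCV-chosen smoothing via smooth.spline.

#' Fit a cubic spline curve to one feature's time series
#'
#' @param times strictly increasing observation times (days).
#' @param values observed values (same length; NA pairs are dropped).
#' @param smoothing `"gcv"` (smoothing parameter chosen by generalized
#'   cross-validation) or `"none"` (exact interpolation).
#' @param subject,layer,feature optional provenance labels.
#' @return a `Curve` object, evaluable on `[min(times), max(times)]` via
#'   [eval_curve()].
#' @export
fit_bspline <- function(times, values, smoothing = c("gcv", "none"),
                        subject = NA_character_, layer = NA_character_,
                        feature = NA_character_) {
  smoothing <- match.arg(smoothing)
  ok <- is.finite(times) & !is.na(values)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 5) {
    stop("fit_bspline needs >= 5 measured time points (got ",
         length(times), ")")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("fit_bspline: times must be strictly increasing")
  }
  if (smoothing == "none") {
    fn <- stats::splinefun(times, values, method = "fmm")
    coefs <- values
  } else {
    fit <- suppressWarnings(
      stats::smooth.spline(times, values, all.knots = TRUE, cv = FALSE,
                           keep.data = FALSE))
    fn <- function(t) stats::predict(fit, t)$y
    coefs <- fit$fit$coef
  }
  structure(list(subject = subject, layer = layer, feature = feature,
                 knots = times, coefficients = coefs,
                 domain = range(times), n_observed = length(times),
                 smoothing = smoothing, fn = fn),
            class = "Curve")
}

#' Evaluate a fitted curve
#'
#' @param curve a `Curve` from [fit_bspline()].
#' @param t evaluation times; must lie inside the curve domain.
#' @return numeric vector of curve values.
#' @export
eval_curve <- function(curve, t) {
  tol <- 1e-8
  if (any(t < curve$domain[1] - tol | t > curve$domain[2] + tol)) {
    stop("eval_curve: time outside curve domain [",
         curve$domain[1], ", ", curve$domain[2], "]")
  }
  curve$fn(pmin(pmax(t, curve$domain[1]), curve$domain[2]))
}

#' Resample a curve on a uniform grid
#'
#' The grid is `{origin, origin + rate, ...}` intersected with the curve
#' domain; no extrapolation is performed. For relative-abundance curves,
#' negative spline excursions can be clipped to zero.
#'
#' @param curve a `Curve`.
#' @param rate_days grid spacing in days (e.g. 14 or 1).
#' @param grid_origin grid origin time; default the domain start.
#' @param clip_negative clip negative values to 0 (relative mode only).
#' @return a `SampledSeries`: list with `times`, `values`, `provenance`.
#' @export
resample <- function(curve, rate_days, grid_origin = NULL,
                     clip_negative = FALSE) {
  if (is.null(grid_origin)) grid_origin <- curve$domain[1]
  grid <- grid_times(curve$domain, rate_days, grid_origin)
  if (!length(grid)) {
    stop("resample: empty grid (origin ", grid_origin, ", rate ", rate_days,
         " vs domain [", curve$domain[1], ", ", curve$domain[2], "])")
  }
  v <- eval_curve(curve, grid)
  if (clip_negative) v <- pmax(v, 0)
  structure(list(times = grid, values = v,
                 provenance = paste(curve$subject, curve$layer, curve$feature,
                                    sep = "/")),
            class = "SampledSeries")
}

grid_times <- function(domain, rate_days, origin) {
  stopifnot(rate_days > 0)
  tol <- 1e-9
  k0 <- max(0, ceiling((domain[1] - origin) / rate_days - tol))
  k1 <- floor((domain[2] - origin) / rate_days + tol)
  if (k1 < k0) return(numeric(0))
  origin + (k0:k1) * rate_days
}
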
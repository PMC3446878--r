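#' Smoothing settings for the upper-envelope Savitzky-Golay filter
#'
#' Mirrors the TIMESAT-style parameters: `window` is the number of points on
#' each side of the fitted point (so the full window holds `2*window + 1`
#' composites), `polyDegree` the local polynomial degree,
#' `envelopeIterations` the number of upper-envelope adaptation passes and
#' `adaptationStrength` the (positive) strength with which points below the
#' current fit are down-weighted.
#'
#' @param window half-window in points on each side (default 5).
#' @param polyDegree local polynomial degree (default 2).
#' @param envelopeIterations number of envelope passes (default 3).
#' @param adaptationStrength positive real (default 3); larger values are more
#'   tolerant of points below the fit.
#' @return a validated list of class `"SmoothingConfig"`.
#' @seealso [smoothUpperEnvelope()]
#' @export
smoothingControl <- function(window = 5L, polyDegree = 2L,
                             envelopeIterations = 3L,
                             adaptationStrength = 3) {
  window <- as.integer(window)
  polyDegree <- as.integer(polyDegree)
  envelopeIterations <- as.integer(envelopeIterations)
  if (window < polyDegree)
    stop("'window' must be at least 'polyDegree'")
  if (envelopeIterations < 0L)
    stop("'envelopeIterations' must be >= 0")
  if (!is.finite(adaptationStrength) || adaptationStrength <= 0)
    stop("'adaptationStrength' must be positive")
  structure(list(window = window, polyDegree = polyDegree,
                 envelopeIterations = envelopeIterations,
                 adaptationStrength = adaptationStrength),
            class = "SmoothingConfig")
}

## Weighted local polynomial fit at every point: the Savitzky-Golay filter on
## an arbitrary (possibly uneven) time axis, with truncated asymmetric windows
## at the series boundaries.
.localPolyFit <- function(time, values, weights, window, degree) {
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - window):min(n, i + window)
    tt <- time[j] - time[i]
    w <- weights[j]
    deg <- min(degree, length(j) - 1L)
    X <- outer(tt, 0:deg, `^`)
    fit <- stats::lm.wfit(X, values[j], w)
    out[i] <- fit$coefficients[1L]
  }
  out
}

## Linear gap-fill of missing composites; >maxGap consecutive missing is fatal.
.fillGaps <- function(time, values, maxGap = 3L) {
  miss <- !is.finite(values)
  if (!any(miss)) return(list(values = values, filled = miss))
  r <- rle(miss)
  if (any(r$values & r$lengths > maxGap))
    stop(sprintf("more than %d consecutive missing composites; refusing to gap-fill",
                 maxGap))
  if (sum(!miss) < 2L) stop("too few observed composites to gap-fill")
  filled <- approx(time[!miss], values[!miss], xout = time, rule = 2)$y
  values[miss] <- filled[miss]
  list(values = values, filled = miss)
}

#' Upper-envelope Savitzky-Golay smoothing of an EVI series
#'
#' Fits a weighted local polynomial (Savitzky-Golay) curve to the composite
#' series and then iteratively adapts it toward the upper envelope of the
#' data: after each pass, points lying below the current fit are down-weighted
#' with \deqn{w_i = 1 / (1 + (g_i / (s\,\sigma))^2)} where \eqn{g_i} is the gap
#' below the fit, \eqn{s} the adaptation strength and \eqn{\sigma} the residual
#' standard deviation of the current pass; points at or above the fit keep
#' weight 1. Weights only ever decay across passes (the new weight is the
#' minimum of the previous and the candidate weight), so the total weight mass
#' is non-increasing. This compensates the negative bias that clouds and poor
#' atmospheric conditions impose on vegetation-index composites.
#'
#' Missing composites (`NA`) are linearly gap-filled first and flagged; more
#' than `maxGap` consecutive missing composites is an error. Boundary points
#' are fitted with truncated asymmetric windows.
#'
#' @param series an [EviSeries-class] with at least `2*window + 1` composites.
#' @param cfg a [smoothingControl()] list.
#' @param maxGap largest run of missing composites that will be gap-filled.
#' @return the series with `smoothed`, `weights` and `filled` slots set.
#' @examples
#' t <- seq(8, by = 16, length.out = 46)
#' v <- 0.2 + 0.4 * exp(-((t - 368) / 120)^2)
#' v[c(10, 20)] <- v[c(10, 20)] - 0.3   # cloud-like negative spikes
#' sm <- smoothUpperEnvelope(EviSeries(values = v, time = t))
#' sm
#' @export
smoothUpperEnvelope <- function(series, cfg = smoothingControl(),
                                maxGap = 3L) {
  stopifnot(is(series, "EviSeries"), inherits(cfg, "SmoothingConfig"))
  n <- length(series@values)
  if (n < 2L * cfg$window + 1L)
    stop(sprintf("series has %d composites; at least %d are required for window %d",
                 n, 2L * cfg$window + 1L, cfg$window))
  gf <- .fillGaps(series@time, series@values, maxGap = maxGap)
  v <- gf$values
  w <- rep(1, n)
  fit <- .localPolyFit(series@time, v, w, cfg$window, cfg$polyDegree)
  for (k in seq_len(cfg$envelopeIterations)) {
    resid <- v - fit
    sigma <- sd(resid)
    if (!is.finite(sigma) || sigma <= 0) break
    gap <- pmax(0, -resid)
    cand <- 1 / (1 + (gap / (cfg$adaptationStrength * sigma))^2)
    w <- pmin(w, cand)
    fit <- .localPolyFit(series@time, v, w, cfg$window, cfg$polyDegree)
  }
  series@values <- gf$values
  series@filled <- gf$filled
  series@smoothed <- fit
  series@weights <- w
  validObject(series)
  series
}

#' Smoothed values of an EVI series
#' @param series an [EviSeries-class].
#' @return the smoothed curve (errors when the series is unsmoothed).
#' @export
smoothedValues <- function(series) {
  stopifnot(is(series, "EviSeries"))
  if (!length(series@smoothed))
    stop("series has not been smoothed; call smoothUpperEnvelope() first")
  series@smoothed
}

#' @describeIn smoothedValues raw EVI values.
#' @export
eviValues <- function(series) {
  stopifnot(is(series, "EviSeries"))
  series@values
}

#' @describeIn smoothedValues sample times in days (composite mid-points).
#' @export
eviTime <- function(series) {
  stopifnot(is(series, "EviSeries"))
  series@time
}
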
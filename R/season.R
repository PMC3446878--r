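## Integral of the piecewise-linear interpolant of (time, values) over
## [t0, t1], with partial trapezoids at both ends.
.trapIntegral <- function(time, values, t0, t1) {
  if (t1 < t0) stop("interval end precedes interval start")
  if (t0 < time[1L] || t1 > time[length(time)])
    stop(sprintf("interval [%.2f, %.2f] outside the series span [%.2f, %.2f]",
                 t0, t1, time[1L], time[length(time)]))
  knots <- time[time > t0 & time < t1]
  tt <- c(t0, knots, t1)
  vv <- approx(time, values, xout = tt)$y
  sum(diff(tt) * (head(vv, -1L) + vv[-1L]) / 2)
}

#' Detect the growing season of a smoothed EVI curve
#'
#' The base level is the mean of the pre-season and post-season minima (the
#' minima left and right of the seasonal maximum), the amplitude is the
#' seasonal maximum minus the base level, and the season limits are the times
#' where the smoothed curve crosses `base + threshold * amplitude` on the
#' rising and falling limbs, linearly interpolated between composites. With
#' the default threshold 0.167 (1/6) this matches the amplitude-fraction
#' season definition used for vegetation-index phenology.
#'
#' @param series a smoothed [EviSeries-class].
#' @param threshold amplitude fraction defining start and end (default 0.167).
#' @param minAmplitude smallest seasonal amplitude (EVI units) accepted as a
#'   season; flat or nearly flat curves raise a "no season detected" error.
#' @return a [GrowingSeason-class].
#' @seealso [computeIevi()]
#' @export
detectGrowingSeason <- function(series, threshold = 0.167,
                                minAmplitude = 0.02) {
  stopifnot(is(series, "EviSeries"))
  sm <- smoothedValues(series)
  tt <- series@time
  imax <- which.max(sm)
  leftMin <- min(sm[seq_len(imax)])
  rightMin <- min(sm[imax:length(sm)])
  base <- (leftMin + rightMin) / 2
  amplitude <- sm[imax] - base
  if (amplitude <= minAmplitude)
    stop(sprintf("no season detected: amplitude %.4f <= %.4f", amplitude,
                 minAmplitude))
  level <- base + threshold * amplitude
  ## rising limb: last upward crossing of `level` before the maximum
  start <- tt[1L]
  for (j in rev(seq_len(imax - 1L))) {
    if (sm[j] < level && sm[j + 1L] >= level) {
      start <- tt[j] + (level - sm[j]) / (sm[j + 1L] - sm[j]) *
        (tt[j + 1L] - tt[j])
      break
    }
  }
  ## falling limb: first downward crossing after the maximum
  end <- tt[length(tt)]
  for (j in imax:(length(sm) - 1L)) {
    if (sm[j] >= level && sm[j + 1L] < level) {
      end <- tt[j] + (sm[j] - level) / (sm[j] - sm[j + 1L]) *
        (tt[j + 1L] - tt[j])
      break
    }
  }
  new("GrowingSeason", startTime = start, endTime = end, baseLevel = base,
      amplitude = amplitude, threshold = threshold)
}

#' Growing-season integrated EVI (iEVI)
#'
#' Trapezoidal integral of the smoothed curve from
#' `start + startFraction * (end - start)` to the season end, in EVI x days.
#' The default `startFraction = 1/6` skips the first sixth of the season, the
#' green-up portion whose EVI mostly reflects stored rather than incident
#' precipitation; `startFraction = 0` gives the complete-growing-season iEVI
#' used by [rescaleB()].
#'
#' @param series a smoothed [EviSeries-class].
#' @param season a [GrowingSeason-class] lying within the series span.
#' @param startFraction fraction of the season skipped at the start
#'   (default 1/6).
#' @return a single non-negative number (when the curve is non-negative).
#' @export
computeIevi <- function(series, season, startFraction = 1 / 6) {
  stopifnot(is(series, "EviSeries"), is(season, "GrowingSeason"))
  if (startFraction < 0 || startFraction >= 1)
    stop("'startFraction' must lie in [0, 1)")
  tLo <- season@startTime +
    startFraction * (season@endTime - season@startTime)
  .trapIntegral(series@time, smoothedValues(series), tLo, season@endTime)
}

#' Integrate a smoothed EVI curve over sampling intervals
#'
#' Computes the per-interval trapezoidal integral of the smoothed curve, i.e.
#' the iEVI covariate at the same temporal scale as the precipitation
#' sampling. Additivity holds exactly: the parts of a partition sum to the
#' integral over the whole span.
#'
#' @param series a smoothed [EviSeries-class].
#' @param intervals two-column object (matrix or data.frame) of interval
#'   start and end times; either numeric days on the series time axis or
#'   `Date`s. Intervals must be non-overlapping and within the series span.
#' @return numeric vector of integrated EVI values (EVI x days), one per
#'   interval.
#' @export
aggregateToIntervals <- function(series, intervals) {
  stopifnot(is(series, "EviSeries"))
  iv <- as.data.frame(intervals)[, 1:2]
  if (inherits(iv[[1L]], "Date")) iv[[1L]] <- as.numeric(iv[[1L]])
  if (inherits(iv[[2L]], "Date")) iv[[2L]] <- as.numeric(iv[[2L]])
  s <- as.numeric(iv[[1L]]); e <- as.numeric(iv[[2L]])
  if (any(e <= s)) stop("intervals must be well-ordered (start < end)")
  o <- order(s)
  if (any(s[o][-1L] < e[o][-length(e)]))
    stop("intervals must be non-overlapping")
  sm <- smoothedValues(series)
  vapply(seq_along(s), function(i) {
    tryCatch(.trapIntegral(series@time, sm, s[i], e[i]),
             error = function(err)
               stop(sprintf("interval %d [%.1f, %.1f]: %s", i, s[i], e[i],
                            conditionMessage(err)), call. = FALSE))
  }, numeric(1))
}
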
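## Shared fixtures, all built in code at test time.

## A double-logistic curve on the composite mid-point axis of one cycle.
dlCurve <- function(t, base = 0.18, amplitude = 0.5, sos = 95, eos = 295,
                    rateUp = 12, rateDown = 15) {
  doubleLogistic(t, base, amplitude, sos, eos, rateUp, rateDown)
}

compositeAxis <- function(nYears = 1L) seq(8, by = 16, length.out = 23L * nYears)

## An EviSeries whose smoothed slot is set directly (bypasses the filter, for
## tests of downstream stages that take a smoothed curve as given).
presmoothed <- function(values, time = seq_along(values) - 1, smoothed = values,
                        siteId = "fix") {
  es <- EviSeries(values = values, time = as.numeric(time), siteId = siteId)
  es@smoothed <- as.numeric(smoothed)
  es@weights <- rep(1, length(values))
  methods::validObject(es)
  es
}

## Reference constants row as IsoModelParams.
refParams <- function(row) {
  tab <- referenceConstants()
  isoParams(tab$a[row], tab$b[row], tab$c[row], tab$d[row], tab$e[row])
}

## Cheap fit configuration for tests that only need a working optimizer.
quickFit <- function(seed = 1L, restarts = 3L) {
  fitControl(restarts = restarts, aFloorGrid = 0.0005, dMinGrid = -0.3,
             dMaxGrid = 0.3, seed = seed)
}

## Independent weighted local-polynomial least squares at one point (oracle
## for the Savitzky-Golay kernel), written against base lm().
wlsAt <- function(time, values, weights, i, window, degree) {
  j <- max(1, i - window):min(length(values), i + window)
  df <- data.frame(tt = time[j] - time[i], v = values[j])
  unname(predict(lm(v ~ poly(tt, degree, raw = TRUE), data = df,
                    weights = weights[j]),
                 newdata = data.frame(tt = 0)))
}

## Observation table for one pixel of an EVI stack, generated through the
## scalar pipeline (smooth -> seasons -> intervals -> covariate -> model).
makePixelObs <- function(stack, row, col, years, params, obsPerSeason = 6L,
                         noiseSd = 0, seed = 1L) {
  sm <- smoothUpperEnvelope(pixelSeries(stack, row, col))
  yr <- as.integer(format(sm@dates, "%Y"))
  out <- list()
  for (y in years) {
    chunk <- sm
    chunk@time <- sm@time[yr == y]; chunk@dates <- sm@dates[yr == y]
    chunk@values <- sm@values[yr == y]; chunk@smoothed <- sm@smoothed[yr == y]
    chunk@weights <- sm@weights[yr == y]; chunk@filled <- sm@filled[yr == y]
    season <- detectGrowingSeason(chunk)
    bounds <- seq(season@startTime, season@endTime,
                  length.out = obsPerSeason + 1L)
    iv <- cbind(head(bounds, -1), bounds[-1])
    x <- aggregateToIntervals(sm, iv)
    out[[length(out) + 1L]] <- data.frame(
      site_id = sprintf("r%dc%d", row, col), year = y,
      start = iv[, 1], end = iv[, 2],
      d18o = simulateD18O(params, x, noiseSd = noiseSd, seed = seed + y))
  }
  do.call(rbind, out)
}
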
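#' Fit the d18O-elevation (lapse) relation for one time step
#'
#' Ordinary least squares of d18O on elevation across anchor sites; with the
#' altitude effect this lapse is typically a few per-mil per km (negative).
#'
#' @param elevation anchor elevations in m a.s.l. (>= 2 distinct values).
#' @param d18o anchor d18O values (per-mil), same length.
#' @param timeStep label of the time step the relation belongs to.
#' @return an [ElevationRelation-class].
#' @export
fitElevationRelation <- function(elevation, d18o, timeStep = "") {
  if (length(elevation) < 2L || length(d18o) != length(elevation))
    stop("need >= 2 (elevation, d18o) anchors of equal length")
  if (diff(range(elevation)) == 0)
    stop("degenerate anchors: all elevations identical")
  fit <- lm(d18o ~ elevation)
  tss <- sum((d18o - mean(d18o))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  new("ElevationRelation",
      intercept = unname(coef(fit)[1L]), lapse = unname(coef(fit)[2L]),
      rSquared = r2, timeStep = as.character(timeStep),
      elevRange = range(elevation))
}

#' Predict d18O at an elevation from a lapse relation
#'
#' @param relation an [ElevationRelation-class].
#' @param elevation elevation(s) in m.
#' @return predicted d18O (per-mil) with attribute `"extrapolated"`, a
#'   logical flag per value marking elevations outside the anchor range.
#' @export
predictAtElevation <- function(relation, elevation) {
  stopifnot(is(relation, "ElevationRelation"))
  out <- relation@intercept + relation@lapse * elevation
  attr(out, "extrapolated") <- elevation < relation@elevRange[1L] |
    elevation > relation@elevRange[2L]
  out
}

## Validate the anchors table used by the raster pipeline.
.checkAnchors <- function(anchors) {
  need <- c("site_id", "elevation", "a", "b", "c", "d", "e", "model_ievi")
  miss <- setdiff(need, names(anchors))
  if (length(miss))
    stop("anchors table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(anchors$model_ievi <= 0))
    stop("anchor model-season iEVI must be positive")
  anchors
}

## Scalar pipeline for one pixel: smooth, season, interval covariate,
## nearest-anchor prediction with per-pixel b rescaling, lapse adjustment.
.pixelD18O <- function(series, elev, anchors, interval, relation = NULL,
                       smoothCfg = smoothingControl(),
                       seasonThreshold = 0.167, minAmplitude = 0.02) {
  sm <- smoothUpperEnvelope(series, smoothCfg)
  season <- detectGrowingSeason(sm, threshold = seasonThreshold,
                                minAmplitude = minAmplitude)
  x <- aggregateToIntervals(sm, matrix(interval, ncol = 2L))
  predIevi <- computeIevi(sm, season, startFraction = 0)
  k <- which.min(abs(anchors$elevation - elev))
  p0 <- isoParams(anchors$a[k], anchors$b[k], anchors$c[k], anchors$d[k],
                  anchors$e[k])
  p <- rescaleParams(p0, anchors$model_ievi[k], predIevi)
  val <- predictD18O(p, x)
  if (!is.null(relation))
    val <- val + relation@lapse * (elev - anchors$elevation[k])
  val
}

#' Rasterise a d18O isoscape from an EVI stack and a DEM
#'
#' For every pixel: smooth the pixel's composite series, detect its growing
#' season, integrate the smoothed curve over the requested time step to get
#' the iEVI covariate, predict d18O with the function of the nearest anchor
#' station in elevation (kink location `b` rescaled to the pixel's
#' complete-season iEVI), and optionally shift the prediction along the
#' d18O-elevation lapse relation by the elevation difference between pixel
#' and anchor. Pixels whose series yields no growing season (or fails
#' validation) are masked as nodata.
#'
#' @param stack an [EviStack-class] of co-registered composites.
#' @param dem elevation matrix on the same grid as `stack` (m a.s.l.).
#' @param anchors data.frame of fitted site functions with columns
#'   `site_id, elevation, a, b, c, d, e, model_ievi` (the complete
#'   growing-season iEVI of each anchor's training season).
#' @param interval length-2 vector (numeric days or `Date`) delimiting the
#'   16-day or monthly step to predict.
#' @param relation optional [ElevationRelation-class] used for the elevation
#'   adjustment; `NULL` (default) disables the adjustment.
#' @param smoothCfg,seasonThreshold,minAmplitude forwarded to the per-pixel
#'   smoothing and season detection.
#' @return an [IsoscapeGrid-class] on the stack's grid.
#' @export
buildIsoscape <- function(stack, dem, anchors, interval, relation = NULL,
                          smoothCfg = smoothingControl(),
                          seasonThreshold = 0.167, minAmplitude = 0.02) {
  stopifnot(is(stack, "EviStack"))
  d <- dim(stack@data)
  if (!is.matrix(dem) || nrow(dem) != d[1L] || ncol(dem) != d[2L])
    stop(sprintf("grid mismatch: DEM is %s, stack is %d x %d",
                 paste(dim(dem), collapse = " x "), d[1L], d[2L]))
  anchors <- .checkAnchors(anchors)
  if (inherits(interval, "Date")) interval <- as.numeric(interval)
  vals <- matrix(NA_real_, d[1L], d[2L])
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    vals[i, j] <- tryCatch(
      .pixelD18O(pixelSeries(stack, i, j), dem[i, j], anchors, interval,
                 relation, smoothCfg, seasonThreshold, minAmplitude),
      error = function(e) NA_real_)
  }
  new("IsoscapeGrid", values = vals, xll = stack@xll, yll = stack@yll,
      cellsize = stack@cellsize, crs = stack@crs, nodata = -9999,
      timeStep = sprintf("%s..%s", as.Date(interval[1L], origin = "1970-01-01"),
                         as.Date(interval[2L], origin = "1970-01-01")))
}

## Fit/predict cycle for one pixel's EVI against one site's observations:
## train on `trainYear`, predict all other years, return pooled Pearson r.
.pixelPredictability <- function(series, siteObs, trainYear, fitCfg,
                                 smoothCfg = smoothingControl(),
                                 seasonThreshold = 0.167, trainPairs = 4L) {
  sm <- smoothUpperEnvelope(series, smoothCfg)
  yearsOfDate <- as.integer(format(sm@dates, "%Y"))
  years <- sort(unique(siteObs$year))
  seasons <- lapply(years, function(y)
    detectGrowingSeason(.subsetSeries(sm, which(yearsOfDate == y)),
                        threshold = seasonThreshold))
  names(seasons) <- as.character(years)
  ievi <- vapply(seasons, function(s)
    computeIevi(sm, s, startFraction = 0), numeric(1))
  tr <- siteObs[siteObs$year == trainYear, , drop = FALSE]
  trSeason <- seasons[[as.character(trainYear)]]
  idx <- if (is.na(trainPairs)) seq_len(nrow(tr)) else
    selectTrainingPairs(tr$start, tr$end, trSeason)
  xTr <- aggregateToIntervals(sm, tr[idx, c("start", "end")])
  fit <- fitIsoModel(xTr, tr$d18o[idx], cfg = fitCfg,
                     minObs = min(5L, length(idx)))
  pred <- obs <- numeric()
  for (y in setdiff(years, trainYear)) {
    tg <- siteObs[siteObs$year == y, , drop = FALSE]
    p <- rescaleParams(fit, ievi[[as.character(trainYear)]],
                       ievi[[as.character(y)]])
    xTg <- aggregateToIntervals(sm, tg[, c("start", "end")])
    pred <- c(pred, predictD18O(p, xTg))
    obs <- c(obs, tg$d18o)
  }
  pearsonPredictability(pred, obs)
}

#' Focal-pixel vs neighbouring-pixel predictability
#'
#' For each site, reruns the complete fit/predict cycle with the EVI series
#' of every pixel in a square ring around the site's focal pixel (Chebyshev
#' distance `ring`: 8 pixels at one cell, 16 at two cells) and compares the
#' resulting cross-season predictability with the focal pixel's:
#' `deltaR = r(ring pixel) - r(focal)`. Ring pixels falling outside the
#' raster are skipped with a warning and counted.
#'
#' @param stack an [EviStack-class].
#' @param sitePixels data.frame `site_id, row, col` locating each site's
#'   focal pixel in the stack.
#' @param obs observation data.frame `site_id, year, start, end, d18o`
#'   (times in days on the stack's composite axis).
#' @param trainYear year whose growing season trains each fit.
#' @param ring ring distance in pixels (1 = 250 m, 2 = 500 m neighbours).
#' @param fitCfg a [fitControl()] list.
#' @param smoothCfg,seasonThreshold forwarded to the pixel pipeline.
#' @param trainPairs 4 for the seasonal four-pair design, `NA` to train on
#'   all in-season observations.
#' @return a list: `meanDelta`, `se`, `p` (two-sided one-sample t-test of
#'   the pooled deltas against 0), `n` ring pixels used, `nSkipped`, and the
#'   pooled `deltas` themselves.
#' @export
neighborhoodSensitivity <- function(stack, sitePixels, obs, trainYear,
                                    ring = 1L, fitCfg = fitControl(),
                                    smoothCfg = smoothingControl(),
                                    seasonThreshold = 0.167,
                                    trainPairs = 4L) {
  stopifnot(is(stack, "EviStack"), ring >= 1L)
  d <- dim(stack@data)
  deltas <- numeric(); nSkipped <- 0L
  for (s in seq_len(nrow(sitePixels))) {
    id <- sitePixels$site_id[s]
    siteObs <- obs[obs$site_id == id, , drop = FALSE]
    r0 <- sitePixels$row[s]; c0 <- sitePixels$col[s]
    rFocal <- .pixelPredictability(pixelSeries(stack, r0, c0), siteObs,
                                   trainYear, fitCfg, smoothCfg,
                                   seasonThreshold, trainPairs)
    offs <- expand.grid(dr = -ring:ring, dc = -ring:ring)
    offs <- offs[pmax(abs(offs$dr), abs(offs$dc)) == ring, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      ri <- r0 + offs$dr[k]; ci <- c0 + offs$dc[k]
      if (ri < 1L || ri > d[1L] || ci < 1L || ci > d[2L]) {
        nSkipped <- nSkipped + 1L
        next
      }
      rRing <- tryCatch(
        .pixelPredictability(pixelSeries(stack, ri, ci), siteObs, trainYear,
                             fitCfg, smoothCfg, seasonThreshold, trainPairs),
        error = function(e) NA_real_)
      if (is.na(rRing)) { nSkipped <- nSkipped + 1L; next }
      deltas <- c(deltas, rRing - rFocal)
    }
  }
  if (nSkipped > 0L)
    warning(sprintf("%d ring pixel(s) skipped (outside raster or failed)",
                    nSkipped))
  n <- length(deltas)
  list(meanDelta = mean(deltas),
       se = if (n > 1L) sd(deltas) / sqrt(n) else NA_real_,
       p = if (n > 1L && sd(deltas) > 0) t.test(deltas)$p.value else NA_real_,
       n = n, nSkipped = nSkipped, deltas = deltas)
}
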
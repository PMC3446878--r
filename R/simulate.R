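#' Double-logistic seasonal EVI curve
#'
#' The canonical unimodal green-up/senescence shape used to emulate a
#' vegetation-index annual cycle:
#' \deqn{f(t) = base + amplitude\left(\frac{1}{1+e^{-(t-sos)/rateUp}} +
#'   \frac{1}{1+e^{(t-eos)/rateDown}} - 1\right)}
#' with `t` in day-of-year.
#'
#' @param t day-of-year (numeric, vectorised).
#' @param base winter background EVI.
#' @param amplitude seasonal amplitude (EVI units, positive).
#' @param sos,eos inflection days of green-up and senescence (`sos < eos`).
#' @param rateUp,rateDown transition widths in days (positive).
#' @return EVI values, same length as `t`.
#' @export
doubleLogistic <- function(t, base = 0.2, amplitude = 0.4, sos = 100,
                           eos = 290, rateUp = 12, rateDown = 15) {
  if (eos <= sos) stop("season end 'eos' must come after season start 'sos'")
  if (amplitude <= 0 || rateUp <= 0 || rateDown <= 0)
    stop("'amplitude', 'rateUp' and 'rateDown' must be positive")
  base + amplitude * (1 / (1 + exp(-(t - sos) / rateUp)) +
                      1 / (1 + exp((t - eos) / rateDown)) - 1)
}

## Composite start dates: a strictly periodic 16-day grid of 23 composites
## per cycle (368-day year), anchored at Jan 1 of the first year. The real
## product restarts the grid every calendar year, which makes the boundary
## gap leap-dependent; the synthetic system uses the exactly periodic grid so
## that noise-free years are numerically identical.
.compositeDates <- function(years) {
  as.Date(sprintf("%d-01-01", years[1L])) +
    16L * (0:(23L * length(years) - 1L))
}

#' Simulate a 16-day EVI composite series
#'
#' Samples a double-logistic annual cycle at the 23 composite mid-points of
#' each 16-day compositing cycle (nominal day-of-year 9, 25, ..., 361; the
#' grid is strictly periodic across years) and adds Gaussian noise plus
#' occasional negative-only "cloud" spikes, the contamination pattern that
#' motivates upper-envelope smoothing.
#'
#' @param years calendar years to simulate (e.g. `2007:2009`).
#' @param curve named list of [doubleLogistic()] parameters
#'   (`base, amplitude, sos, eos, rateUp, rateDown`).
#' @param noiseSd standard deviation of additive Gaussian noise (EVI units).
#' @param spikeProb per-composite probability of a cloud spike.
#' @param spikeMag mean magnitude of a (negative) cloud spike; the actual
#'   depression is uniform on `[0.5, 1.5] * spikeMag`.
#' @param seed integer seed; same seed, same series.
#' @param siteId identifier for the resulting series.
#' @return an unsmoothed [EviSeries-class] (23 composites per year).
#' @export
simulateEviCurve <- function(years, curve = list(), noiseSd = 0.02,
                             spikeProb = 0.05, spikeMag = 0.3, seed = 1L,
                             siteId = "sim") {
  stopifnot(noiseSd >= 0, spikeProb >= 0, spikeProb <= 1, spikeMag >= 0)
  cp <- utils::modifyList(lapply(as.list(formals(doubleLogistic))[-1L], eval),
                          curve)
  dates <- .compositeDates(years)
  ## cycle day of each composite mid-point (nominal day-of-year)
  doy <- (as.numeric(dates - dates[1L]) %% 368) + 9
  clean <- doubleLogistic(doy, cp$base, cp$amplitude, cp$sos, cp$eos,
                          cp$rateUp, cp$rateDown)
  v <- .withLocalSeed(seed, {
    out <- clean + rnorm(length(clean), 0, noiseSd)
    spikes <- runif(length(clean)) < spikeProb
    out[spikes] <- out[spikes] -
      runif(sum(spikes), 0.5, 1.5) * spikeMag
    out
  })
  EviSeries(values = v, dates = dates, siteId = siteId)
}

#' Simulate a station network along an elevation gradient
#'
#' Places `nSites` stations evenly along the elevation range and assigns each
#' a full set of iEVI-d18O constants by piecewise-linear interpolation of the
#' [referenceConstants()] columns against station rank; with the default 13
#' sites the reference rows are returned exactly.
#'
#' @param nSites number of stations (default 13).
#' @param elevRange elevation range in m a.s.l. (default `c(91, 2876)`).
#' @param constants source table of constants (columns `station,a,b,c,d,e`),
#'   default [referenceConstants()].
#' @return a list with `stations` (data.frame `site_id, lon, lat, elevation`)
#'   and `params` (named list of [IsoModelParams-class], one per station).
#' @export
simulateStationNetwork <- function(nSites = 13L, elevRange = c(91, 2876),
                                   constants = referenceConstants()) {
  nSites <- as.integer(nSites)
  stopifnot(nSites >= 1L, nrow(constants) >= 1L)
  nref <- nrow(constants)
  rank <- if (nSites == 1L) 1 else seq(1, nref, length.out = nSites)
  cols <- c("a", "b", "c", "d", "e")
  interp <- vapply(cols, function(cn) {
    if (nref == 1L) rep(constants[[cn]], nSites)
    else approx(seq_len(nref), constants[[cn]], xout = rank)$y
  }, numeric(nSites))
  interp <- matrix(interp, nrow = nSites,
                   dimnames = list(NULL, cols))
  elev <- if (nSites == 1L) elevRange[1L] else
    seq(elevRange[1L], elevRange[2L], length.out = nSites)
  ids <- sprintf("s%d", seq_len(nSites))
  stations <- data.frame(
    site_id = ids,
    lon = 121.2 + seq(0, 0.25, length.out = nSites),
    lat = 24.2 - seq(0, 0.2, length.out = nSites),
    elevation = elev, stringsAsFactors = FALSE)
  params <- lapply(seq_len(nSites), function(i)
    .rowToParams(as.list(interp[i, ])))
  names(params) <- ids
  list(stations = stations, params = params)
}

#' Simulate d18O observations from a site model
#'
#' Inverts the prediction step: observed d18O is the model value at the
#' interval's iEVI covariate plus Gaussian measurement/weather noise, with an
#' optional heavy-rain outlier mechanism that depletes (makes more negative)
#' a random subset of observations — the tropical-cyclone analogue.
#'
#' @param params an [IsoModelParams-class].
#' @param x iEVI covariates, one per sampling interval.
#' @param noiseSd observation noise sd in per-mil (default 0.5).
#' @param outlierProb probability an observation is an outlier (default 0).
#' @param outlierDepletion per-mil subtracted from outliers (default 5).
#' @param seed integer seed.
#' @return numeric vector of simulated d18O (per-mil).
#' @export
simulateD18O <- function(params, x, noiseSd = 0.5, outlierProb = 0,
                         outlierDepletion = 5, seed = 1L) {
  stopifnot(is(params, "IsoModelParams"), noiseSd >= 0,
            outlierProb >= 0, outlierProb <= 1, outlierDepletion >= 0)
  mu <- predictD18O(params, x)
  .withLocalSeed(seed, {
    y <- mu + rnorm(length(x), 0, noiseSd)
    out <- runif(length(x)) < outlierProb
    y[out] <- y[out] - outlierDepletion
    y
  })
}

.subsetSeries <- function(series, idx) {
  new("EviSeries", siteId = series@siteId, time = series@time[idx],
      dates = if (length(series@dates)) series@dates[idx] else series@dates,
      values = series@values[idx],
      smoothed = if (length(series@smoothed)) series@smoothed[idx]
                 else numeric(),
      weights = if (length(series@weights)) series@weights[idx]
                else numeric(),
      filled = series@filled[idx])
}

## Per-site double-logistic parameters along the elevation gradient: higher
## stations green up later, senesce earlier and reach lower peak EVI.
.elevCurveParams <- function(frac) {
  list(base = 0.18,
       amplitude = 0.55 - 0.20 * frac,
       sos = 85 + 25 * frac,
       eos = 305 - 25 * frac,
       rateUp = 12, rateDown = 15)
}

#' Simulate a complete virtual study system
#'
#' Builds the full model-consistent network every pipeline stage can be
#' tested on: stations along the elevation gradient with interpolated site
#' constants, multi-year EVI series (smoothed with `smoothCfg`), per-year
#' growing seasons, roughly-monthly sampling intervals inside each season,
#' iEVI covariates computed by the package's own aggregation, and d18O
#' observations generated from each site's model plus noise and optional
#' heavy-rain outliers.
#'
#' One replicate year is simulated on each side of `years` before smoothing
#' and dropped afterwards, so the retained years carry no filter edge
#' effects. With all noise switched off the observations lie exactly on the
#' site models and every growing season of a site is identical, which is the
#' basis of the pipeline's closure identity.
#'
#' @param years calendar years retained (default `2007:2009`).
#' @param nSites number of stations (default 13).
#' @param obsPerSeason sampling intervals per growing season (default 6,
#'   approximately monthly).
#' @param eviNoiseSd,cloudSpikeProb,cloudSpikeMag EVI noise controls, passed
#'   to [simulateEviCurve()] (defaults 0.015, 0.08, 0.3).
#' @param d18oNoiseSd,outlierProb,outlierDepletion observation noise controls
#'   passed to [simulateD18O()] (defaults 0.5, 0.03, 5).
#' @param smoothCfg a [smoothingControl()] list.
#' @param seasonThreshold amplitude fraction for season limits (default 0.167).
#' @param elevRange elevation span in m (default `c(91, 2876)`).
#' @param seed integer master seed; per-site streams are derived from it.
#' @return a list: `stations`, `params` (list of [IsoModelParams-class]),
#'   `series` (smoothed [EviSeries-class] per site), `seasons` (per site, a
#'   named list of [GrowingSeason-class] keyed by year), `obs` (data.frame
#'   `site_id, year, start, end, x, d18o`; times in days on the series axis),
#'   and `seasonIevi` (data.frame `site_id, year, completeIevi`).
#' @export
simulateIsoNetwork <- function(years = 2007:2009, nSites = 13L,
                               obsPerSeason = 6L,
                               eviNoiseSd = 0.015, cloudSpikeProb = 0.08,
                               cloudSpikeMag = 0.3,
                               d18oNoiseSd = 0.5, outlierProb = 0.03,
                               outlierDepletion = 5,
                               smoothCfg = smoothingControl(),
                               seasonThreshold = 0.167,
                               elevRange = c(91, 2876), seed = 1L) {
  stopifnot(obsPerSeason >= 1L)
  net <- simulateStationNetwork(nSites = nSites, elevRange = elevRange)
  padYears <- (min(years) - 1L):(max(years) + 1L)
  frac <- if (nSites == 1L) 0 else
    (seq_len(nSites) - 1) / (nSites - 1)
  obs <- list(); seasons <- list(); series <- list(); sIevi <- list()
  for (i in seq_len(nSites)) {
    id <- net$stations$site_id[i]
    es <- simulateEviCurve(padYears, curve = .elevCurveParams(frac[i]),
                           noiseSd = eviNoiseSd, spikeProb = cloudSpikeProb,
                           spikeMag = cloudSpikeMag,
                           seed = seed + 1000L * i, siteId = id)
    es <- smoothUpperEnvelope(es, smoothCfg)
    padLabel <- rep(padYears, each = 23L)
    es <- .subsetSeries(es, which(padLabel %in% years))
    series[[id]] <- es
    yearsOfDate <- padLabel[padLabel %in% years]
    seasons[[id]] <- list()
    for (y in years) {
      chunk <- .subsetSeries(es, which(yearsOfDate == y))
      season <- detectGrowingSeason(chunk, threshold = seasonThreshold)
      seasons[[id]][[as.character(y)]] <- season
      bounds <- seq(season@startTime, season@endTime,
                    length.out = obsPerSeason + 1L)
      iv <- cbind(utils::head(bounds, -1L), bounds[-1L])
      x <- aggregateToIntervals(es, iv)
      d18o <- simulateD18O(net$params[[id]], x, noiseSd = d18oNoiseSd,
                           outlierProb = outlierProb,
                           outlierDepletion = outlierDepletion,
                           seed = seed + 1000L * i + y)
      obs[[length(obs) + 1L]] <- data.frame(
        site_id = id, year = y, start = iv[, 1L], end = iv[, 2L],
        x = x, d18o = d18o, stringsAsFactors = FALSE)
      sIevi[[length(sIevi) + 1L]] <- data.frame(
        site_id = id, year = y,
        completeIevi = computeIevi(es, season, startFraction = 0),
        stringsAsFactors = FALSE)
    }
  }
  list(stations = net$stations, params = net$params, series = series,
       seasons = seasons, obs = do.call(rbind, obs),
       seasonIevi = do.call(rbind, sIevi))
}

#' Simulate a co-registered EVI stack and DEM
#'
#' Builds a small synthetic scene for the raster pipeline: a smooth synthetic
#' DEM (a ridge running along the grid) and, per pixel, a double-logistic EVI
#' cycle whose amplitude decreases monotonically with elevation, sampled into
#' 16-day composites with optional noise.
#'
#' @param nrow,ncol grid size in pixels (default 20 x 20).
#' @param years calendar years of composites (default 2007).
#' @param elevRange DEM range in m (default `c(100, 2800)`).
#' @param eviNoiseSd,spikeProb,spikeMag noise controls per pixel series
#'   (defaults 0, 0, 0.3 — a clean scene unless asked otherwise).
#' @param cellsize cell edge in CRS units (default 250).
#' @param xll,yll lower-left corner (default 0, 0).
#' @param crs CRS description (default the MODIS sinusoidal grid).
#' @param seed integer seed.
#' @return a list with `stack` (an [EviStack-class]) and `dem` (numeric
#'   matrix, row 1 northernmost, same grid as the stack).
#' @export
simulateRasterStack <- function(nrow = 20L, ncol = 20L, years = 2007L,
                                elevRange = c(100, 2800), eviNoiseSd = 0,
                                spikeProb = 0, spikeMag = 0.3,
                                cellsize = 250, xll = 0, yll = 0,
                                crs = "MODIS sinusoidal", seed = 1L) {
  dem <- outer(seq_len(nrow), seq_len(ncol), function(i, j)
    elevRange[1L] + (elevRange[2L] - elevRange[1L]) *
      (0.65 * (j - 1) / max(1L, ncol - 1L) +
       0.35 * sin(pi * (i - 0.5) / nrow)^2))
  dem <- pmin(dem, elevRange[2L])
  dates <- .compositeDates(years)
  nt <- length(dates)
  data <- array(NA_real_, dim = c(nrow, ncol, nt))
  span <- diff(elevRange)
  for (i in seq_len(nrow)) for (j in seq_len(ncol)) {
    frac <- if (span > 0) (dem[i, j] - elevRange[1L]) / span else 0
    es <- simulateEviCurve(years, curve = .elevCurveParams(frac),
                           noiseSd = eviNoiseSd, spikeProb = spikeProb,
                           spikeMag = spikeMag,
                           seed = seed + 7919L * i + 104729L * j)
    data[i, j, ] <- es@values
  }
  stack <- new("EviStack", data = data, dates = dates, xll = xll, yll = yll,
               cellsize = cellsize, crs = crs)
  list(stack = stack, dem = dem)
}
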
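#' Pearson predictability of d18O predictions
#'
#' @param pred predicted d18O (per-mil).
#' @param obs observed d18O (per-mil), same length, >= 3 pairs.
#' @return the Pearson product-moment correlation coefficient.
#' @export
pearsonPredictability <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("'pred' and 'obs' lengths differ")
  if (length(pred) < 3L)
    stop("need at least 3 prediction/observation pairs")
  if (sd(pred) == 0 || sd(obs) == 0)
    stop("undefined correlation: zero variance on one side")
  cor(pred, obs)
}

#' Remove at most one extreme observation per season
#'
#' Heavy-rain events (tropical cyclones) produce strongly depleted d18O
#' values that destabilise temporal predictability comparisons. Per season,
#' the observation with the largest absolute robust z-score of d18O
#' (median/MAD based) is removed — and only when that z-score exceeds
#' `zThreshold` — so that never more than one observation per season is
#' excluded. Seasons with zero spread are left untouched by convention.
#'
#' @param d18o observed d18O values.
#' @param season season (or site-season) label per observation.
#' @param zThreshold robust z-score threshold (default 3).
#' @return a list: `keep` (logical vector, `FALSE` on removed observations)
#'   and `log` (data.frame `season, index, d18o, z` of every removal).
#' @export
excludeExtrema <- function(d18o, season, zThreshold = 3) {
  if (length(d18o) != length(season))
    stop("'d18o' and 'season' lengths differ")
  keep <- rep(TRUE, length(d18o))
  logs <- list()
  for (s in unique(season)) {
    idx <- which(season == s)
    v <- d18o[idx]
    md <- median(v)
    spread <- median(abs(v - md)) * 1.4826
    if (!is.finite(spread) || spread <= 0) next
    z <- (v - md) / spread
    worst <- which.max(abs(z))
    if (abs(z[worst]) > zThreshold) {
      keep[idx[worst]] <- FALSE
      logs[[length(logs) + 1L]] <- data.frame(
        season = s, index = idx[worst], d18o = v[worst], z = z[worst],
        stringsAsFactors = FALSE)
    }
  }
  list(keep = keep,
       log = if (length(logs)) do.call(rbind, logs)
             else data.frame(season = character(), index = integer(),
                             d18o = numeric(), z = numeric(),
                             stringsAsFactors = FALSE))
}

## Aggregate paired predictions/observations to a coarser temporal unit by
## interval-length-weighted means within each unit.
.aggregatePairs <- function(df, unit) {
  w <- df$end - df$start
  agg <- function(v) vapply(split(seq_len(nrow(df)), unit), function(i)
    sum(v[i] * w[i]) / sum(w[i]), numeric(1))
  data.frame(unit = names(split(seq_len(nrow(df)), unit)),
             pred = agg(df$pred), obs = agg(df$obs),
             stringsAsFactors = FALSE)
}

.safeR <- function(pred, obs) {
  if (length(pred) < 3L || sd(pred) == 0 || sd(obs) == 0) return(NA_real_)
  cor(pred, obs)
}

#' Cross-validate the iEVI-d18O model over a station network
#'
#' Reproduces the cross-season predictability design: per site, observations
#' of the training season fit the site function (four training pairs by
#' default — beginning, two middle, end of the growing season), the kink
#' location is rescaled to each target season's complete-season iEVI, all
#' target-season intervals are predicted, and Pearson predictability is
#' reported at the 16-day, monthly, seasonal and annual aggregation scales.
#' Extreme observations (at most one per season) are excluded before the
#' correlations.
#'
#' @param network a virtual or assembled study system as returned by
#'   [simulateIsoNetwork()]: `series` (smoothed [EviSeries-class] per site),
#'   `seasons` (per site, [GrowingSeason-class] per year), `obs` (data.frame
#'   `site_id, year, start, end, d18o`) and `stations`.
#' @param trainYear the growing season used for model building.
#' @param fitCfg a [fitControl()] list.
#' @param trainPairs 4 (default) for the seasonal four-pair design; `NA`
#'   trains on all in-season observations of the training year.
#' @param zThreshold extrema-exclusion threshold (see [excludeExtrema()]).
#' @return a list:
#'   \describe{
#'     \item{perSite}{data.frame `site_id, scale, r, n` (site-level r is `NA`
#'       where fewer than 3 pairs or zero variance remain).}
#'     \item{pooled}{data.frame `scale, r, n, mean_r, se_r` pooling all sites;
#'       `mean_r`/`se_r` summarise the per-site correlations.}
#'     \item{excluded}{the extrema-exclusion log.}
#'     \item{skipped}{data.frame `site_id, reason` of sites that could not be
#'       cross-validated.}
#'   }
#' @export
crossValidateNetwork <- function(network, trainYear, fitCfg = fitControl(),
                                 trainPairs = 4L, zThreshold = 3) {
  obs <- network$obs
  years <- sort(unique(obs$year))
  targetYears <- setdiff(years, trainYear)
  if (!length(targetYears)) stop("no target seasons besides the training year")
  pairs <- list(); skipped <- list()
  for (id in unique(obs$site_id)) {
    res <- tryCatch({
      siteObs <- obs[obs$site_id == id, , drop = FALSE]
      sm <- network$series[[id]]
      seasons <- network$seasons[[id]]
      tr <- siteObs[siteObs$year == trainYear, , drop = FALSE]
      trSeason <- seasons[[as.character(trainYear)]]
      idx <- if (is.na(trainPairs)) seq_len(nrow(tr)) else
        selectTrainingPairs(tr$start, tr$end, trSeason)
      xTr <- aggregateToIntervals(sm, tr[idx, c("start", "end")])
      fit <- fitIsoModel(xTr, tr$d18o[idx], cfg = fitCfg,
                         minObs = min(5L, length(idx)))
      trIevi <- computeIevi(sm, trSeason, startFraction = 0)
      out <- list()
      for (y in targetYears) {
        tg <- siteObs[siteObs$year == y, , drop = FALSE]
        if (!nrow(tg)) next
        p <- rescaleParams(fit, trIevi,
                           computeIevi(sm, seasons[[as.character(y)]],
                                       startFraction = 0))
        xTg <- aggregateToIntervals(sm, tg[, c("start", "end")])
        out[[length(out) + 1L]] <- data.frame(
          site_id = id, year = y, start = tg$start, end = tg$end,
          pred = predictD18O(p, xTg), obs = tg$d18o,
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }, error = function(e) conditionMessage(e))
    if (is.character(res))
      skipped[[length(skipped) + 1L]] <- data.frame(
        site_id = id, reason = res, stringsAsFactors = FALSE)
    else pairs[[length(pairs) + 1L]] <- res
  }
  if (!length(pairs)) stop("no site could be cross-validated")
  df <- do.call(rbind, pairs)
  ## season = site-year; exclude at most one extreme observation per season
  seasonId <- paste(df$site_id, df$year, sep = ":")
  excl <- excludeExtrema(df$obs, seasonId, zThreshold = zThreshold)
  df <- df[excl$keep, , drop = FALSE]
  mid <- as.Date((df$start + df$end) / 2, origin = "1970-01-01")
  df$`16-day` <- sprintf("%.0f", df$start)
  df$monthly <- format(mid, "%Y-%m")
  df$seasonal <- df$annual <- sprintf("%d", df$year)
  perSite <- list(); pooled <- list()
  for (sc in c("16-day", "monthly", "seasonal", "annual")) {
    aggAll <- do.call(rbind, lapply(split(df, df$site_id), function(sdf) {
      cbind(site_id = sdf$site_id[1L], .aggregatePairs(sdf, sdf[[sc]]))
    }))
    rSite <- vapply(split(aggAll, aggAll$site_id), function(a)
      .safeR(a$pred, a$obs), numeric(1))
    perSite[[sc]] <- data.frame(
      site_id = names(rSite), scale = sc, r = unname(rSite),
      n = as.integer(table(aggAll$site_id)[names(rSite)]),
      stringsAsFactors = FALSE)
    rPool <- .safeR(aggAll$pred, aggAll$obs)
    ok <- !is.na(rSite)
    pooled[[sc]] <- data.frame(
      scale = sc, r = rPool, n = nrow(aggAll),
      mean_r = if (any(ok)) mean(rSite[ok]) else NA_real_,
      se_r = if (sum(ok) > 1L) sd(rSite[ok]) / sqrt(sum(ok)) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(perSite = do.call(rbind, perSite),
       pooled = do.call(rbind, pooled),
       excluded = excl$log,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(site_id = character(), reason = character(),
                                 stringsAsFactors = FALSE))
}

#' Correlation between temporal EVI and d18O variability across sites
#'
#' Temporal stability is summarised per site as the standard deviation of
#' the multi-year EVI series and of the d18O series; the statistic is the
#' Pearson correlation of the two standard deviations across sites.
#'
#' @param eviSd per-site standard deviation of the (multi-year) EVI series —
#'   or a list of [EviSeries-class] from which it is computed.
#' @param d18oSd per-site standard deviation of the d18O series — or a list /
#'   data.frame of per-site d18O vectors.
#' @return Pearson correlation across sites.
#' @export
variabilityCorrelation <- function(eviSd, d18oSd) {
  if (is.list(eviSd) && !is.data.frame(eviSd))
    eviSd <- vapply(eviSd, function(s) sd(eviValues(s)), numeric(1))
  if (is.list(d18oSd) && !is.data.frame(d18oSd))
    d18oSd <- vapply(d18oSd, sd, numeric(1))
  if (length(eviSd) < 3L) stop("need at least 3 sites")
  if (length(eviSd) != length(d18oSd)) stop("site counts differ")
  if (sd(eviSd) == 0 || sd(d18oSd) == 0)
    stop("undefined correlation: identical variabilities across sites")
  cor(eviSd, d18oSd)
}

#' Local meteoric water line
#'
#' Ordinary least squares of dD on d18O; on the global line the slope is 8
#' and the intercept (deuterium excess) 10.
#'
#' @param d18o,dD paired isotope values (per-mil), >= 3 pairs.
#' @return a list with `slope`, `intercept`, `residuals` and `rSquared`.
#' @export
meteoricWaterLine <- function(d18o, dD) {
  if (length(d18o) != length(dD)) stop("'d18o' and 'dD' lengths differ")
  if (length(d18o) < 3L) stop("need at least 3 (d18o, dD) pairs")
  if (sd(d18o) == 0) stop("degenerate d18o variance")
  fit <- lm(dD ~ d18o)
  res <- unname(stats::residuals(fit))
  tss <- sum((dD - mean(dD))^2)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       residuals = res,
       rSquared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_)
}
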
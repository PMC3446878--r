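test_that("Pearson predictability matches the covariance formula and guards", {
  expect_equal(pearsonPredictability(c(-3, -5, -9), c(-3, -5, -9)), 1)
  expect_equal(pearsonPredictability(c(-3, -5, -9), c(3, 5, 9)), -1)
  p <- c(-2.1, -4.3, -6.2, -8.8, -5.5)
  o <- c(-2.5, -4.0, -6.9, -8.1, -5.0)
  oracle <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  expect_equal(pearsonPredictability(p, o), oracle, tolerance = 1e-12)
  expect_error(pearsonPredictability(c(-3, -3, -3), o[1:3]), "zero variance")
  expect_error(pearsonPredictability(p[1:2], o[1:2]), "at least 3")
  ## r is invariant to affine rescaling of the predictions
  expect_equal(pearsonPredictability(2.5 * p - 7, o),
               pearsonPredictability(p, o), tolerance = 1e-12)
})

test_that("extrema exclusion removes at most the single worst point per season", {
  ## no outlier: unchanged
  d <- c(-4, -5, -4.5, -5.2, -4.8)
  r <- excludeExtrema(d, rep("s1:2007", 5))
  expect_true(all(r$keep))
  expect_equal(nrow(r$log), 0L)
  ## two extreme values in one season: only the most extreme goes
  d2 <- c(-4, -5, -4.5, -15, -11)
  r2 <- excludeExtrema(d2, rep("s1:2007", 5))
  expect_equal(which(!r2$keep), 4L)
  expect_equal(sum(!r2$keep), 1L)
  expect_equal(r2$log$season, "s1:2007")
  ## constant season: zero spread, nothing removed by convention
  r3 <- excludeExtrema(rep(-6, 4), rep("s", 4))
  expect_true(all(r3$keep))
  ## across many random seasons, never more than one removal per season
  set.seed(12)
  d4 <- rnorm(300, -6, 2) - 8 * rbinom(300, 1, 0.1)
  s4 <- rep(sprintf("s%d", 1:30), each = 10)
  r4 <- excludeExtrema(d4, s4)
  expect_true(all(table(r4$log$season) <= 1))
  perSeason <- tapply(!r4$keep, s4, sum)
  expect_true(all(perSeason <= 1))
})

test_that("noise-free model-consistent network cross-validates to r = 1", {
  net <- simulateIsoNetwork(years = 2007:2009, nSites = 4, eviNoiseSd = 0,
                            cloudSpikeProb = 0, d18oNoiseSd = 0,
                            outlierProb = 0, seed = 21)
  cv <- crossValidateNetwork(net, 2007, fitCfg = quickFit(seed = 2,
                                                          restarts = 4),
                             trainPairs = NA)
  expect_true(all(cv$pooled$r > 1 - 1e-9))
  ok <- !is.na(cv$perSite$r)
  expect_true(any(ok))
  expect_true(all(cv$perSite$r[ok] > 1 - 1e-9))
  expect_equal(nrow(cv$skipped), 0L)
})

test_that("sites with too few training observations are skipped with a reason", {
  net <- simulateIsoNetwork(years = 2007:2008, nSites = 3, eviNoiseSd = 0,
                            cloudSpikeProb = 0, d18oNoiseSd = 0,
                            outlierProb = 0, seed = 22)
  ## degrade one site to 3 in-season training observations
  idx <- which(net$obs$site_id == "s2" & net$obs$year == 2007)[1:3]
  net$obs <- net$obs[-idx, ]
  cv <- crossValidateNetwork(net, 2007, fitCfg = quickFit(seed = 3,
                                                          restarts = 3))
  expect_true("s2" %in% cv$skipped$site_id)
  expect_match(cv$skipped$reason[cv$skipped$site_id == "s2"], "insufficient")
  expect_false("s2" %in% cv$perSite$site_id)
})

test_that("aggregation to coarser scales improves noisy predictability on average", {
  deltas <- vapply(1:8, function(rep) {
    net <- simulateIsoNetwork(years = 2007:2009, nSites = 5, eviNoiseSd = 0,
                              cloudSpikeProb = 0, d18oNoiseSd = 0.5,
                              outlierProb = 0, seed = 400 + rep)
    cv <- crossValidateNetwork(net, 2007,
                               fitCfg = quickFit(seed = rep, restarts = 3),
                               trainPairs = NA)
    p <- cv$pooled
    p$r[p$scale == "annual"] - p$r[p$scale == "16-day"]
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("variability correlation across sites matches direct arithmetic", {
  expect_error(variabilityCorrelation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(variabilityCorrelation(rep(0.1, 5), rep(0.3, 5)), "undefined")
  ## perfectly proportional spreads
  expect_equal(variabilityCorrelation(1:5 * 0.01, 1:5 * 0.7), 1)
  ## 13 synthetic sites with elevation-linked variability, formula oracle
  set.seed(33)
  eviSd <- 0.02 + 0.01 * (1:13) + rnorm(13, 0, 0.004)
  d18oSd <- 0.5 + 0.2 * (1:13) + rnorm(13, 0, 0.15)
  oracle <- sum((eviSd - mean(eviSd)) * (d18oSd - mean(d18oSd))) /
    sqrt(sum((eviSd - mean(eviSd))^2) * sum((d18oSd - mean(d18oSd))^2))
  expect_equal(variabilityCorrelation(eviSd, d18oSd), oracle,
               tolerance = 1e-12)
  ## list-of-series input computes per-site sds itself
  sers <- lapply(1:4, function(k)
    EviSeries(values = k * 0.01 * sin(1:46) + 0.3,
              time = compositeAxis(2)))
  d18o <- lapply(1:4, function(k) k * c(-4, -6, -8, -5))
  expect_equal(variabilityCorrelation(sers, d18o), 1, tolerance = 1e-12)
})

test_that("meteoric water line recovers the global line and the OLS oracle", {
  d18o <- seq(-12, -3, length.out = 8)
  dD <- 8 * d18o + 10
  mwl <- meteoricWaterLine(d18o, dD)
  expect_equal(mwl$slope, 8, tolerance = 1e-10)
  expect_equal(mwl$intercept, 10, tolerance = 1e-10)
  expect_equal(mwl$residuals, rep(0, 8), tolerance = 1e-10)
  expect_error(meteoricWaterLine(d18o[1:2], dD[1:2]), "at least 3")
  expect_error(meteoricWaterLine(rep(-5, 4), c(-30, -31, -29, -33)),
               "degenerate")
  set.seed(14)
  dDn <- 8 * d18o + 10 + rnorm(8, 0, 2)
  m <- meteoricWaterLine(d18o, dDn)
  sxx <- sum((d18o - mean(d18o))^2)
  slope <- sum((d18o - mean(d18o)) * (dDn - mean(dDn))) / sxx
  expect_equal(m$slope, slope, tolerance = 1e-10)
  expect_equal(m$intercept, mean(dDn) - slope * mean(d18o), tolerance = 1e-10)
})
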
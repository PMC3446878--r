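test_that("elevation relation reproduces lines and matches normal equations", {
  ## two anchors: exact interpolating line
  rel <- fitElevationRelation(c(91, 2876), c(-4.2, -11.9))
  expect_equal(predictAtElevation(rel, 91)[1], -4.2, tolerance = 1e-10)
  expect_equal(predictAtElevation(rel, 2876)[1], -11.9, tolerance = 1e-10)
  ## midpoint of two anchors is the mean of their values
  expect_equal(predictAtElevation(rel, (91 + 2876) / 2)[1],
               (-4.2 - 11.9) / 2, tolerance = 1e-10)
  ## three collinear anchors: zero residual, r^2 = 1
  e3 <- c(91, 1676, 2876)
  y3 <- -3 - 0.003 * e3
  rel3 <- fitElevationRelation(e3, y3)
  expect_equal(rel3@lapse, -0.003, tolerance = 1e-12)
  expect_equal(rel3@rSquared, 1, tolerance = 1e-12)
  ## noisy anchors vs closed-form 2x2 normal-equations solve
  set.seed(8)
  yn <- -3 - 0.003 * e3 + rnorm(3, 0, 0.4)
  reln <- fitElevationRelation(e3, yn)
  sxx <- sum((e3 - mean(e3))^2)
  slope <- sum((e3 - mean(e3)) * (yn - mean(yn))) / sxx
  expect_equal(reln@lapse, slope, tolerance = 1e-10)
  expect_equal(reln@intercept, mean(yn) - slope * mean(e3), tolerance = 1e-10)
  ## degenerate and zero-lapse cases
  expect_error(fitElevationRelation(c(500, 500), c(-5, -6)), "identical")
  flat <- fitElevationRelation(c(100, 200), c(-5, -5))
  expect_equal(as.vector(predictAtElevation(flat, c(0, 5000))), c(-5, -5))
  expect_identical(attr(predictAtElevation(flat, c(150, 5000)),
                        "extrapolated"), c(FALSE, TRUE))
})

test_that("raster pipeline equals the looped scalar pipeline pixelwise", {
  sc <- simulateRasterStack(nrow = 6, ncol = 6, years = 2007, seed = 3)
  tab <- referenceConstants()
  anchors <- data.frame(site_id = c("lo", "mid", "hi"),
                        elevation = c(91, 1676, 2876),
                        tab[c(1, 7, 13), c("a", "b", "c", "d", "e")],
                        model_ievi = c(120, 95, 70))
  rel <- fitElevationRelation(c(91, 1676, 2876), c(-4, -8, -12))
  iv <- as.numeric(sc$stack@dates[c(14, 15)])
  grid <- buildIsoscape(sc$stack, sc$dem, anchors, iv, relation = rel)
  ## scalar oracle: rebuild each pixel's value from exported primitives only
  for (i in c(1, 4, 6)) for (j in c(2, 5)) {
    sm <- smoothUpperEnvelope(pixelSeries(sc$stack, i, j))
    season <- detectGrowingSeason(sm)
    x <- aggregateToIntervals(sm, matrix(iv, ncol = 2))
    predIevi <- computeIevi(sm, season, startFraction = 0)
    k <- which.min(abs(anchors$elevation - sc$dem[i, j]))
    p <- rescaleParams(isoParams(anchors$a[k], anchors$b[k], anchors$c[k],
                                 anchors$d[k], anchors$e[k]),
                       anchors$model_ievi[k], predIevi)
    want <- predictD18O(p, x) + rel@lapse * (sc$dem[i, j] - anchors$elevation[k])
    expect_equal(grid@values[i, j], want, tolerance = 1e-9)
  }
  expect_true(all(is.finite(grid@values)))
})

test_that("uniform scene with flat DEM gives a constant raster equal to the site prediction", {
  sc <- simulateRasterStack(nrow = 3, ncol = 3, years = 2007,
                            elevRange = c(800, 800), seed = 5)
  expect_true(all(sc$dem == 800))
  expect_equal(sc$stack@data[1, 1, ], sc$stack@data[3, 2, ])
  tab <- referenceConstants()
  anchors <- data.frame(site_id = "a", elevation = 800,
                        tab[5, c("a", "b", "c", "d", "e")], model_ievi = 100)
  iv <- as.numeric(sc$stack@dates[c(14, 15)])
  grid <- buildIsoscape(sc$stack, sc$dem, anchors, iv)
  expect_equal(max(grid@values) - min(grid@values), 0, tolerance = 1e-12)
  ## equals the scalar site-level prediction
  sm <- smoothUpperEnvelope(pixelSeries(sc$stack, 2, 2))
  x <- aggregateToIntervals(sm, matrix(iv, ncol = 2))
  predIevi <- computeIevi(sm, detectGrowingSeason(sm), startFraction = 0)
  p <- rescaleParams(refParams(5), 100, predIevi)
  expect_equal(grid@values[1, 1], predictD18O(p, x), tolerance = 1e-9)
})

test_that("grid mismatch and broken anchor tables are rejected", {
  sc <- simulateRasterStack(nrow = 4, ncol = 4, years = 2007, seed = 2)
  tab <- referenceConstants()
  anchors <- data.frame(site_id = "a", elevation = 500,
                        tab[1, c("a", "b", "c", "d", "e")], model_ievi = 100)
  iv <- as.numeric(sc$stack@dates[c(14, 15)])
  expect_error(buildIsoscape(sc$stack, sc$dem[1:3, ], anchors, iv),
               "grid mismatch")
  expect_error(buildIsoscape(sc$stack, sc$dem, anchors[, -8], iv),
               "model_ievi")
  badAnchors <- anchors; badAnchors$model_ievi <- -1
  expect_error(buildIsoscape(sc$stack, sc$dem, badAnchors, iv), "positive")
})

test_that("identical ring pixels give zero predictability difference", {
  sc <- simulateRasterStack(nrow = 5, ncol = 5, years = 2007:2008,
                            elevRange = c(800, 800), seed = 6)
  obs <- makePixelObs(sc$stack, 3, 3, 2007:2008, refParams(5), noiseSd = 0)
  sens <- neighborhoodSensitivity(
    sc$stack, data.frame(site_id = "r3c3", row = 3, col = 3), obs,
    trainYear = 2007, ring = 1L, fitCfg = quickFit(seed = 2, restarts = 2),
    trainPairs = NA)
  expect_equal(sens$n, 8L)
  expect_equal(sens$deltas, rep(0, 8), tolerance = 1e-9)
})

test_that("noise-corrupted ring pixels predict worse than the focal pixel", {
  sc <- simulateRasterStack(nrow = 5, ncol = 5, years = 2007:2008,
                            elevRange = c(800, 800), seed = 7)
  ## corrupt every pixel except the focal one with heavy EVI noise
  set.seed(41)
  for (i in 1:5) for (j in 1:5) {
    if (i == 3 && j == 3) next
    nt <- dim(sc$stack@data)[3]
    sc$stack@data[i, j, ] <- pmax(0.02, sc$stack@data[i, j, ] +
      rnorm(nt, 0, 0.08) - 0.35 * rbinom(nt, 1, 0.2))
  }
  obs <- makePixelObs(sc$stack, 3, 3, 2007:2008, refParams(5), noiseSd = 0.3,
                      seed = 13)
  sens <- neighborhoodSensitivity(
    sc$stack, data.frame(site_id = "r3c3", row = 3, col = 3), obs,
    trainYear = 2007, ring = 1L, fitCfg = quickFit(seed = 2, restarts = 2),
    trainPairs = NA)
  expect_lt(sens$meanDelta, 0)
  expect_gt(sens$se, 0)
})

test_that("rings extending beyond the raster are skipped and counted", {
  sc <- simulateRasterStack(nrow = 4, ncol = 4, years = 2007:2008,
                            elevRange = c(800, 800), seed = 8)
  obs <- makePixelObs(sc$stack, 1, 1, 2007:2008, refParams(5), noiseSd = 0)
  expect_warning(
    sens <- neighborhoodSensitivity(
      sc$stack, data.frame(site_id = "r1c1", row = 1, col = 1), obs,
      trainYear = 2007, ring = 1L, fitCfg = quickFit(seed = 2, restarts = 2),
      trainPairs = NA),
    "skipped")
  expect_equal(sens$nSkipped, 5L)
  expect_equal(sens$n, 3L)
})
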
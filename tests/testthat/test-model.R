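test_that("predictD18O evaluates the kinked quadratic exactly", {
  ## hand case: a=1,b=0,c=0,d=0,e=0 is outside the feasibility box, so check
  ## the same arithmetic through the raw slots of a boundary-near parameter
  p <- isoParams(0.001, 20.5, -1e-6, 0, 0.001)
  expect_equal(predictD18O(p, 22.5),
               -0.001 * (abs(22.5 - 20.5) + -1e-6)^2 + 0 * 22.5 - 0.001,
               tolerance = 1e-12)
  ## reference site s1 at its kink: -a*c^2 + d*b - e, direct arithmetic
  s1 <- refParams(1)
  oracle <- -0.003001 * (-74.069)^2 + (-0.00393) * 110.655 - 2.66119
  expect_equal(predictD18O(s1, 110.655), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 2), -19.56)
  ## the non-linear part is symmetric about b
  for (t in c(1, 7.5, 40)) {
    lhs <- predictD18O(s1, 110.655 + t) - s1@d * (110.655 + t)
    rhs <- predictD18O(s1, 110.655 - t) - s1@d * (110.655 - t)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  expect_error(predictD18O(s1, NA_real_), "finite")
})

test_that("parameter bounds are enforced by the class validity", {
  expect_error(isoParams(0.0004, 110, -74, 0, 2), "bounds")
  expect_error(isoParams(0.003, 310, -74, 0, 2), "bounds")
  expect_error(isoParams(0.003, 110, 5, 0, 2), "bounds")
  expect_error(isoParams(0.003, 110, -74, 0.5, 2), "bounds")
  expect_error(isoParams(0.003, 110, -74, 0, 120), "bounds")
  expect_silent(isoParams(0.003, 110, -74, 0, 2))
})

test_that("rootSSE is the unscaled root of summed squares", {
  s1 <- refParams(1)
  x <- c(50, 90, 140)
  y <- predictD18O(s1, x)
  expect_equal(rootSSE(s1, x, y), 0)
  ## single residual r gives |r|
  expect_equal(rootSSE(s1, 50, y[1] + 1.7), 1.7, tolerance = 1e-12)
  ## three toy observations vs spreadsheet-style recomputation
  obs <- y + c(0.3, -0.5, 1.1)
  oracle <- sqrt(0.3^2 + 0.5^2 + 1.1^2)
  expect_equal(rootSSE(s1, x, obs), oracle, tolerance = 1e-12)
  expect_error(rootSSE(s1, numeric(), numeric()), "no observations")
})

test_that("noise-free fits recover randomly drawn generating constants", {
  set.seed(31)
  for (k in 1:3) {
    truth <- isoParams(runif(1, 0.001, 0.008), runif(1, 60, 160),
                       runif(1, -120, -30), runif(1, -0.25, 0.25),
                       runif(1, 1, 20))
    ## design spanning the kink pins all five constants
    x <- seq(truth@b - 70, truth@b + 70, length.out = 24)
    fit <- fitIsoModel(x, predictD18O(truth, x),
                       cfg = fitControl(restarts = 8, seed = 100 + k))
    expect_lt(fit@rootSSE, 1e-6)
    expect_equal(unname(coef(fit)), unname(coef(truth)), tolerance = 1e-3)
    expect_gt(fit@rSquared, 1 - 1e-9)
  }
})

test_that("degenerate fitting inputs raise the documented errors", {
  s1 <- refParams(1)
  x4 <- c(40, 80, 120, 160)
  expect_error(fitIsoModel(x4, predictD18O(s1, x4)), "underdetermined")
  x5 <- rep(80, 5)
  expect_error(fitIsoModel(x5, predictD18O(s1, x5)), "degenerate")
  expect_error(fitIsoModel(c(40, 80, 120, 160, NA),
                           c(-1, -2, -3, -2, -1)), "finite")
})

test_that("fit is deterministic in the seed and monotone in restarts", {
  s1 <- refParams(1)
  x <- seq(30, 200, length.out = 10)
  set.seed(77)
  y <- predictD18O(s1, x) + rnorm(10, 0, 0.4)
  f1 <- fitIsoModel(x, y, cfg = quickFit(seed = 5, restarts = 4))
  f2 <- fitIsoModel(x, y, cfg = quickFit(seed = 5, restarts = 4))
  expect_identical(coef(f1), coef(f2))
  ## per-cell restart streams are nested, so more restarts never hurt
  prev <- Inf
  for (r in c(1, 3, 6)) {
    rss <- fitIsoModel(x, y, cfg = quickFit(seed = 5, restarts = r))@rootSSE
    expect_lte(rss, prev + 1e-12)
    prev <- rss
  }
})

test_that("b-rescaling is the stated ratio rule", {
  expect_equal(rescaleB(110.655, 87.3, 87.3), 110.655)
  expect_equal(rescaleB(110.655, 50, 100), 2 * 110.655)
  expect_error(rescaleB(110.655, 0, 100), "positive")
  ## homogeneous of degree 1 in the prediction-season iEVI
  expect_equal(rescaleB(80, 40, 3 * 55), 3 * rescaleB(80, 40, 55))
  ## parameter-object form carries the other constants unchanged
  p <- rescaleParams(refParams(1), 100, 110)
  expect_equal(p@b, 110.655 * 1.1, tolerance = 1e-12)
  expect_equal(c(p@a, p@c, p@d, p@e),
               c(0.003001, -74.069, -0.00393, 2.66119))
})

test_that("training-pair selection picks beginning, middle pair and end", {
  season <- new("GrowingSeason", startTime = 0, endTime = 1, baseLevel = 0,
                amplitude = 1, threshold = 0.167)
  ## exactly four in-season observations: all of them, in quantile order
  b5 <- seq(0, 1, length.out = 5)
  expect_setequal(selectTrainingPairs(head(b5, -1), b5[-1], season), 1:4)
  ## 12 evenly spaced: nearest midpoints to quantiles {0, .4, .6, 1}
  b13 <- seq(0, 1, length.out = 13)
  idx <- selectTrainingPairs(head(b13, -1), b13[-1], season)
  mid <- (head(b13, -1) + b13[-1]) / 2
  oracle <- vapply(c(0, 0.4, 0.6, 1), function(q)
    which.min(abs(mid - q)), integer(1))
  expect_identical(idx, oracle)
  expect_identical(idx, c(1L, 5L, 8L, 12L))
  expect_identical(anyDuplicated(idx), 0L)
  ## too few in-season observations
  expect_error(selectTrainingPairs(c(0.1, 0.5), c(0.2, 0.6), season),
               "insufficient")
})
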
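#' Predict d18O from iEVI with the five-constant site model
#'
#' Evaluates \deqn{\delta^{18}O(x) = -a\,(|x - b| + c)^2 + d\,x - e,} a
#' kinked-quadratic in the iEVI covariate `x`: continuous everywhere,
#' differentiable except at `x = b`, and symmetric about `b` once the linear
#' trend `d x` is removed.
#'
#' @param params an [IsoModelParams-class] or [FitResult-class].
#' @param x iEVI covariate(s), finite numeric.
#' @return predicted d18O in per-mil (VSMOW), same length as `x`.
#' @examples
#' s <- isoParams(a = 0.003001, b = 110.655, c = -74.069,
#'                d = -0.00393, e = 2.66119)
#' predictD18O(s, c(50, 110.655, 180))
#' @export
setGeneric("predictD18O", function(params, x) standardGeneric("predictD18O"))

#' @rdname predictD18O
#' @export
setMethod("predictD18O", "IsoModelParams", function(params, x) {
  if (any(!is.finite(x))) stop("'x' must be finite")
  -params@a * (abs(x - params@b) + params@c)^2 + params@d * x - params@e
})

#' @rdname predictD18O
#' @export
setMethod("predictD18O", "FitResult", function(params, x) {
  predictD18O(params@params, x)
})

.predictRaw <- function(p, x) -p[1L] * (abs(x - p[2L]) + p[3L])^2 + p[4L] * x - p[5L]

#' Root-SSE fitting objective
#'
#' The square root of the sum of squared residuals between model predictions
#' and observed d18O. Deliberately not divided by the number of observations:
#' this is the exact objective minimised by the site-model fit.
#'
#' @param params an [IsoModelParams-class] (or [FitResult-class]).
#' @param x iEVI covariates.
#' @param d18o observed d18O (per-mil), same length as `x`.
#' @return a single non-negative number (per-mil).
#' @seealso [fitIsoModel()]
#' @export
rootSSE <- function(params, x, d18o) {
  if (!length(x)) stop("no observations supplied")
  if (length(x) != length(d18o)) stop("'x' and 'd18o' lengths differ")
  sqrt(sum((predictD18O(params, x) - d18o)^2))
}

#' Settings for the multi-start constrained fit
#'
#' The fit sweeps a grid of initial-bound cells: every combination of a lower
#' bound on the curvature `a` (`aFloorGrid`, 7 values by default) with lower
#' and upper bounds on the slope `d` (`dMinGrid` x `dMaxGrid`, 3 x 3), giving
#' the default 63 cells. Within each cell, `restarts` bound-constrained local
#' least-squares optimisations are started from uniform-random points inside
#' the cell's parameter box.
#'
#' @param restarts random restarts per grid cell (default 30).
#' @param aFloorGrid lower bounds on `a` (default `seq(0.0005, 0.0035, 0.0005)`).
#' @param dMinGrid lower bounds on `d` (default `c(-0.1, -0.2, -0.3)`).
#' @param dMaxGrid upper bounds on `d` (default `c(0.1, 0.2, 0.3)`).
#' @param aCap upper bound on `a` closing the optimisation box (default 0.01).
#' @param seed integer seed making the restarts reproducible.
#' @param ptol,ftol optimizer tolerances (see [minpack.lm::nls.lm.control()]).
#' @return a validated list of class `"FitConfig"`.
#' @export
fitControl <- function(restarts = 30L,
                       aFloorGrid = seq(0.0005, 0.0035, by = 0.0005),
                       dMinGrid = c(-0.1, -0.2, -0.3),
                       dMaxGrid = c(0.1, 0.2, 0.3),
                       aCap = 0.01, seed = 1L,
                       ptol = 1e-10, ftol = 1e-12) {
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("'restarts' must be >= 1")
  if (!length(aFloorGrid) || !length(dMinGrid) || !length(dMaxGrid))
    stop("initial-bound grids must be non-empty")
  if (any(aFloorGrid < .PARAM_LOWER[["a"]]) || any(aFloorGrid >= aCap))
    stop("'aFloorGrid' must lie in [0.0005, aCap)")
  if (any(dMinGrid <= .PARAM_LOWER[["d"]]) ||
      any(dMaxGrid >= .PARAM_UPPER[["d"]]) || any(dMinGrid >= 0) ||
      any(dMaxGrid <= 0))
    stop("'d' grids must satisfy -0.4 < dMin < 0 < dMax < 0.4")
  structure(list(restarts = restarts, aFloorGrid = aFloorGrid,
                 dMinGrid = dMinGrid, dMaxGrid = dMaxGrid, aCap = aCap,
                 seed = as.integer(seed), ptol = ptol, ftol = ftol),
            class = "FitConfig")
}

## Run a computation with a locally seeded RNG, restoring the caller's stream.
.withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Fit the five-constant iEVI-d18O model by multi-start constrained least squares
#'
#' Minimises the root-SSE objective over the feasibility box
#' `a > aFloor, 20 < b < 300, -200 < c < 0, dMin < d < dMax, 0 < e < 100`
#' for every initial-bound grid cell of `cfg` (63 cells by default), running
#' `cfg$restarts` seeded random-start bound-constrained Levenberg-Marquardt
#' optimisations per cell, keeping each cell's best and returning the global
#' best across cells together with its r-squared (squared Pearson correlation
#' of fitted vs observed d18O). Deterministic given `cfg$seed`.
#'
#' @param x iEVI covariates, one per observation.
#' @param d18o observed d18O (per-mil).
#' @param cfg a [fitControl()] list.
#' @param minObs smallest admissible number of observations. The default 5
#'   matches the five free parameters; the four-pair seasonal training design
#'   of [crossValidateNetwork()] lowers it to 4 deliberately.
#' @return a [FitResult-class].
#' @examples
#' s <- isoParams(0.003001, 110.655, -74.069, -0.00393, 2.66119)
#' x <- seq(30, 200, length.out = 24)
#' fit <- fitIsoModel(x, predictD18O(s, x),
#'                    cfg = fitControl(restarts = 5, seed = 7))
#' coef(fit)
#' @export
fitIsoModel <- function(x, d18o, cfg = fitControl(), minObs = 5L) {
  n <- length(x)
  if (length(d18o) != n) stop("'x' and 'd18o' lengths differ")
  if (n < minObs)
    stop(sprintf("underdetermined fit: %d observations for 5 parameters (need >= %d)",
                 n, minObs))
  if (any(!is.finite(x)) || any(!is.finite(d18o)))
    stop("observations must be finite")
  if (diff(range(x)) == 0)
    stop("degenerate design: all iEVI covariates identical")
  eps <- 1e-9
  cells <- expand.grid(a_floor = cfg$aFloorGrid, d_min = cfg$dMinGrid,
                       d_max = cfg$dMaxGrid, KEEP.OUT.ATTRS = FALSE)
  ## Levenberg-Marquardt needs >= 5 residuals for 5 parameters; structural
  ## zero padding keeps the objective identical for the 4-pair design.
  pad <- rep(0, max(0L, 5L - n))
  resFun <- function(p) c(.predictRaw(p, x) - d18o, pad)
  best <- NULL
  .withLocalSeed(cfg$seed, {
    for (ci in seq_len(nrow(cells))) {
      lower <- c(cells$a_floor[ci] + eps, .PARAM_LOWER[["b"]] + eps,
                 .PARAM_LOWER[["c"]] + eps, cells$d_min[ci] + eps, eps)
      upper <- c(cfg$aCap, .PARAM_UPPER[["b"]] - eps, -eps,
                 cells$d_max[ci] - eps, .PARAM_UPPER[["e"]] - eps)
      for (k in seq_len(cfg$restarts)) {
        p0 <- runif(5L, lower, upper)
        ans <- tryCatch(
          minpack.lm::nls.lm(
            par = p0, lower = lower, upper = upper, fn = resFun,
            control = minpack.lm::nls.lm.control(
              maxiter = 1000L, ptol = cfg$ptol, ftol = cfg$ftol)),
          error = function(e) NULL)
        if (is.null(ans)) next
        rss <- sqrt(sum(ans$fvec^2))
        if (is.null(best) || rss < best$rootSSE)
          best <- list(par = ans$par, rootSSE = rss,
                       cell = c(a_floor = cells$a_floor[ci],
                                d_min = cells$d_min[ci],
                                d_max = cells$d_max[ci]),
                       converged = ans$info %in% 1:4)
      }
    }
  })
  if (is.null(best))
    stop("no restart converged; try more restarts or looser tolerances")
  p <- best$par
  pred <- .predictRaw(p, x)
  r2 <- if (sd(pred) > 0 && sd(d18o) > 0) cor(pred, d18o)^2 else NA_real_
  new("FitResult",
      params = isoParams(p[1L], p[2L], p[3L], p[4L], p[5L]),
      rootSSE = best$rootSSE, rSquared = min(r2, 1),
      nObs = as.integer(n), winningCell = best$cell,
      converged = best$converged)
}

#' Transfer the kink location to another growing season
#'
#' The fitted kink location `b` scales with the size of the growing season it
#' was trained in; when the model is applied to a different season, `b` is
#' rescaled by the ratio of the complete-growing-season iEVIs:
#' \deqn{b_{predict} = b_{model} \cdot
#'   \mathrm{iEVI}_{pred\ season} / \mathrm{iEVI}_{model\ season}.}
#' All other constants carry over unchanged.
#'
#' @param bModel fitted `b` (iEVI units).
#' @param ieviModelSeason complete-growing-season iEVI of the training season
#'   (must be positive).
#' @param ieviPredSeason complete-growing-season iEVI of the season to be
#'   predicted.
#' @return the rescaled `b` (iEVI units).
#' @export
rescaleB <- function(bModel, ieviModelSeason, ieviPredSeason) {
  if (!is.finite(ieviModelSeason) || ieviModelSeason <= 0)
    stop("model-season iEVI must be positive")
  ## ratio first: equal-season transfer is then the exact identity
  bModel * (ieviPredSeason / ieviModelSeason)
}

#' @describeIn rescaleB apply the rescaling to a parameter object, returning a
#'   copy with `b` replaced. The rescaled kink location is allowed to leave
#'   the fitting bounds: those bounds constrain model *building*, while the
#'   transfer rule is exact arithmetic applied at prediction time.
#' @param params an [IsoModelParams-class] or [FitResult-class].
#' @export
rescaleParams <- function(params, ieviModelSeason, ieviPredSeason) {
  if (is(params, "FitResult")) params <- params@params
  stopifnot(is(params, "IsoModelParams"))
  out <- params
  out@b <- rescaleB(params@b, ieviModelSeason, ieviPredSeason)
  out
}

#' Select the four seasonal training observations
#'
#' Mirrors the one-season training design: one observation at the beginning
#' of the growing season, two in the middle and one at the end. Candidates
#' are the observations whose interval midpoint falls inside the season;
#' among those, the ones nearest (in season time) to the quantiles
#' `{0, 0.4, 0.6, 1}` of the season are selected, earliest first on ties,
#' without replacement so all four are distinct.
#'
#' @param start,end interval start and end times of each observation (numeric
#'   days or `Date`).
#' @param season a [GrowingSeason-class].
#' @param quantiles season-time quantiles defining "beginning / middle / end"
#'   (default `c(0, 0.4, 0.6, 1)`).
#' @return integer indices of the selected observations, in quantile order.
#' @export
selectTrainingPairs <- function(start, end, season,
                                quantiles = c(0, 0.4, 0.6, 1)) {
  stopifnot(is(season, "GrowingSeason"))
  if (inherits(start, "Date")) start <- as.numeric(start)
  if (inherits(end, "Date")) end <- as.numeric(end)
  mid <- (start + end) / 2
  inSeason <- which(mid >= season@startTime & mid <= season@endTime)
  if (length(inSeason) < length(quantiles))
    stop(sprintf("insufficient training pairs: %d in-season observations, need %d",
                 length(inSeason), length(quantiles)))
  targets <- season@startTime + quantiles * (season@endTime - season@startTime)
  chosen <- integer()
  for (tq in targets) {
    avail <- setdiff(inSeason, chosen)
    d <- abs(mid[avail] - tq)
    ## ties go to the earlier observation
    cand <- avail[d == min(d)]
    chosen <- c(chosen, cand[which.min(mid[cand])])
  }
  chosen
}
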
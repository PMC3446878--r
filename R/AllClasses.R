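#' @import methods
#' @importFrom stats approx coef cor lm median sd setNames t.test predict runif rnorm rbinom quantile
NULL

.checkScalarFinite <- function(x, what) {
  if (length(x) != 1L || !is.finite(x))
    return(sprintf("'%s' must be a single finite number", what))
  NULL
}

#' One pixel's or site's 16-day EVI time series
#'
#' Holds the dated Enhanced Vegetation Index composites for a single site or
#' raster pixel (nominally 23 composites per year), together with the
#' upper-envelope smoothed curve and the per-point smoothing weights once
#' [smoothUpperEnvelope()] has been applied. Sample times are the composite
#' mid-points, expressed in days.
#'
#' @slot siteId single character identifier.
#' @slot time numeric vector of sample times in days (composite mid-points),
#'   strictly increasing.
#' @slot dates composite start dates (`Date`, may be length 0 when the series
#'   was built from a bare numeric time axis).
#' @slot values raw EVI values (unitless, plausible range -0.2..1); `NA` marks
#'   a missing composite to be gap-filled before smoothing.
#' @slot smoothed fitted upper-envelope curve (length 0 until smoothing).
#' @slot weights final smoothing weights in (0, 1] (length 0 until smoothing).
#' @slot filled logical flags marking gap-filled composites.
#'
#' @seealso [EviSeries()], [smoothUpperEnvelope()], [detectGrowingSeason()]
#' @exportClass EviSeries
setClass("EviSeries",
  representation(
    siteId   = "character",
    time     = "numeric",
    dates    = "Date",
    values   = "numeric",
    smoothed = "numeric",
    weights  = "numeric",
    filled   = "logical"
  )
)

setValidity("EviSeries", function(object) {
  msgs <- character()
  n <- length(object@time)
  if (length(object@siteId) != 1L) msgs <- c(msgs, "siteId must be length 1")
  if (length(object@values) != n)
    msgs <- c(msgs, "time and values must have equal length")
  if (n >= 2L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  if (any(!is.finite(object@time)))
    msgs <- c(msgs, "time must be finite")
  v <- object@values
  if (any(!is.na(v) & !is.finite(v)))
    msgs <- c(msgs, "non-missing values must be finite")
  if (length(object@smoothed) && length(object@smoothed) != n)
    msgs <- c(msgs, "smoothed must match values in length")
  if (length(object@weights) &&
      (length(object@weights) != n ||
       any(object@weights <= 0 | object@weights > 1)))
    msgs <- c(msgs, "weights must match length and lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EVI series
#'
#' @param values numeric EVI values; `NA` marks missing composites.
#' @param dates composite start dates (`Date` or ISO-8601 strings). Sample
#'   times are placed at the composite mid-point, `dates + 8` days, following
#'   the 16-day compositing convention.
#' @param time alternatively, a bare numeric time axis in days (mid-points);
#'   exactly one of `dates`/`time` must be given.
#' @param siteId site or pixel identifier.
#' @return an [EviSeries-class] object (unsmoothed).
#' @examples
#' es <- EviSeries(values = runif(23, 0.2, 0.6),
#'                 dates = as.Date("2007-01-01") + 16 * (0:22))
#' es
#' @export
EviSeries <- function(values, dates = NULL, time = NULL, siteId = "site") {
  if (is.null(dates) == is.null(time))
    stop("give exactly one of 'dates' or 'time'")
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    if (anyNA(dates)) stop("unparseable dates in EVI series")
    time <- as.numeric(dates) + 8
  } else {
    dates <- as.Date(character())
  }
  new("EviSeries",
      siteId = as.character(siteId), time = as.numeric(time), dates = dates,
      values = as.numeric(values), smoothed = numeric(), weights = numeric(),
      filled = logical(length(values)))
}

setMethod("show", "EviSeries", function(object) {
  cat(sprintf("EviSeries '%s': %d composites", object@siteId,
              length(object@values)))
  if (length(object@dates))
    cat(sprintf(" (%s .. %s)", min(object@dates), max(object@dates)))
  cat(if (length(object@smoothed)) ", smoothed\n" else ", raw\n")
  invisible(object)
})

#' Growing season of a smoothed EVI curve
#'
#' Start and end are the times where the smoothed curve crosses
#' `baseLevel + threshold * amplitude` on the rising and falling limbs.
#'
#' @slot startTime,endTime season limits in days (same axis as the series).
#' @slot baseLevel mean of the pre- and post-season minima (EVI units).
#' @slot amplitude seasonal maximum minus base level (EVI units).
#' @slot threshold amplitude fraction defining the season limits.
#' @seealso [detectGrowingSeason()], [computeIevi()]
#' @exportClass GrowingSeason
setClass("GrowingSeason",
  representation(startTime = "numeric", endTime = "numeric",
                 baseLevel = "numeric", amplitude = "numeric",
                 threshold = "numeric")
)

setValidity("GrowingSeason", function(object) {
  msgs <- c(
    .checkScalarFinite(object@startTime, "startTime"),
    .checkScalarFinite(object@endTime, "endTime"),
    .checkScalarFinite(object@amplitude, "amplitude"),
    .checkScalarFinite(object@threshold, "threshold"))
  if (is.null(msgs) || !length(msgs)) {
    if (object@startTime >= object@endTime)
      msgs <- c(msgs, "startTime must precede endTime")
    if (object@amplitude <= 0) msgs <- c(msgs, "amplitude must be positive")
    if (object@threshold <= 0 || object@threshold >= 1)
      msgs <- c(msgs, "threshold must lie in (0, 1)")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GrowingSeason", function(object) {
  cat(sprintf(
    "GrowingSeason: [%.1f, %.1f] d (length %.1f d), base %.3f, amplitude %.3f, threshold %.3f\n",
    object@startTime, object@endTime, object@endTime - object@startTime,
    object@baseLevel, object@amplitude, object@threshold))
  invisible(object)
})

## global feasibility box for the five site constants
.PARAM_LOWER <- c(a = 0.0005, b = 20, c = -200, d = -0.4, e = 0)
.PARAM_UPPER <- c(a = Inf,    b = 300, c = 0,   d = 0.4,  e = 100)

#' The five site constants of the iEVI-d18O function
#'
#' The site-level model is \eqn{\delta^{18}O(x) = -a(|x-b|+c)^2 + dx - e} with
#' iEVI covariate `x`. `a` sets the curvature (per-mil per iEVI^2), `b` the
#' kink location (iEVI units), `c` a negative kink offset (iEVI units), `d` a
#' linear slope (per-mil per iEVI) and `e` an offset (per-mil). Feasibility:
#' `a > 0.0005`, `20 < b < 300`, `-200 < c < 0`, `-0.4 < d < 0.4`,
#' `0 < e < 100`.
#'
#' @slot a,b,c,d,e the five constants (see description).
#' @seealso [isoParams()], [predictD18O()], [fitIsoModel()]
#' @exportClass IsoModelParams
setClass("IsoModelParams",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 d = "numeric", e = "numeric")
)

setValidity("IsoModelParams", function(object) {
  p <- c(a = object@a, b = object@b, c = object@c, d = object@d, e = object@e)
  if (length(p) != 5L || any(!is.finite(p)))
    return("all five constants must be single finite numbers")
  bad <- names(p)[p <= .PARAM_LOWER | p >= .PARAM_UPPER]
  if (length(bad))
    return(sprintf("constants outside feasibility bounds: %s",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' @describeIn IsoModelParams-class constructor.
#' @param a,b,c,d,e the five constants.
#' @export
isoParams <- function(a, b, c, d, e) {
  new("IsoModelParams", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d), e = as.numeric(e))
}

#' @describeIn IsoModelParams-class constants as a named vector.
#' @param object an `IsoModelParams`.
#' @export
setMethod("coef", "IsoModelParams", function(object, ...) {
  c(a = object@a, b = object@b, c = object@c, d = object@d, e = object@e)
})

setMethod("show", "IsoModelParams", function(object) {
  cat("iEVI-d18O site constants:\n")
  print(signif(coef(object), 6))
  invisible(object)
})

#' Result of the multi-start constrained fit
#'
#' @slot params best-fitting [IsoModelParams-class].
#' @slot rootSSE square root of the summed squared residuals (per-mil); this is
#'   the fitting objective and is deliberately not divided by n.
#' @slot rSquared squared Pearson correlation between fitted and observed
#'   d18O (`NA` when degenerate).
#' @slot nObs number of observations fitted.
#' @slot winningCell named numeric triple `(a_floor, d_min, d_max)` of the
#'   initial-bound grid cell that produced the winner.
#' @slot converged did the winning restart converge.
#' @seealso [fitIsoModel()]
#' @exportClass FitResult
setClass("FitResult",
  representation(params = "IsoModelParams", rootSSE = "numeric",
                 rSquared = "numeric", nObs = "integer",
                 winningCell = "numeric", converged = "logical")
)

setValidity("FitResult", function(object) {
  msgs <- character()
  if (length(object@rootSSE) != 1L || !is.finite(object@rootSSE) ||
      object@rootSSE < 0)
    msgs <- c(msgs, "rootSSE must be a single non-negative number")
  r2 <- object@rSquared
  if (length(r2) != 1L || (!is.na(r2) && (r2 < 0 || r2 > 1 + 1e-12)))
    msgs <- c(msgs, "rSquared must be NA or in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FitResult-class fitted constants as a named vector.
#' @param object a `FitResult`.
#' @export
setMethod("coef", "FitResult", function(object, ...) coef(object@params))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("iEVI-d18O fit on %d observations\n", object@nObs))
  print(signif(coef(object), 6))
  cat(sprintf("root-SSE %.4g permil, r^2 %.4f, cell (a>%g, %g<d<%g)%s\n",
              object@rootSSE,
              if (is.na(object@rSquared)) NA_real_ else object@rSquared,
              object@winningCell[["a_floor"]], object@winningCell[["d_min"]],
              object@winningCell[["d_max"]],
              if (object@converged) "" else " [not converged]"))
  invisible(object)
})

#' Linear elevation (lapse) relation for one time step
#'
#' Ordinary least squares of predicted or observed d18O on station elevation:
#' `d18o = intercept + lapse * elevation`.
#'
#' @slot intercept per-mil at sea level.
#' @slot lapse per-mil per metre (the altitude effect; typically negative).
#' @slot rSquared coefficient of determination of the fit.
#' @slot timeStep label of the 16-day or monthly step the relation belongs to.
#' @slot elevRange elevation range (m) spanned by the anchors; predictions
#'   outside it are flagged as extrapolated.
#' @seealso [fitElevationRelation()], [predictAtElevation()]
#' @exportClass ElevationRelation
setClass("ElevationRelation",
  representation(intercept = "numeric", lapse = "numeric",
                 rSquared = "numeric", timeStep = "character",
                 elevRange = "numeric")
)

setValidity("ElevationRelation", function(object) {
  if (!is.finite(object@intercept) || !is.finite(object@lapse))
    return("coefficients must be finite")
  TRUE
})

setMethod("show", "ElevationRelation", function(object) {
  cat(sprintf(
    "Elevation relation [%s]: d18o = %.4f %+.6f * elev (r^2 %.3f, anchors %g-%g m)\n",
    object@timeStep, object@intercept, object@lapse, object@rSquared,
    object@elevRange[1], object@elevRange[2]))
  invisible(object)
})

#' Georeferenced single-band grid of predicted d18O
#'
#' A minimal in-memory raster: a value matrix plus the lower-left corner,
#' cell size and CRS string, i.e. exactly the georeferencing an ESRI ASCII
#' grid carries. Row 1 of `values` is the northernmost row.
#'
#' @slot values numeric matrix of predicted d18O (per-mil); `NA` = nodata.
#' @slot xll,yll coordinates of the lower-left corner of the grid.
#' @slot cellsize cell edge length in CRS units (250 m by default workflow).
#' @slot crs free-text CRS description (PROJ string or EPSG code).
#' @slot nodata value used for nodata when written to disk.
#' @slot timeStep label of the predicted 16-day or monthly step.
#' @seealso [buildIsoscape()], [writeAsciiGrid()], [readAsciiGrid()]
#' @exportClass IsoscapeGrid
setClass("IsoscapeGrid",
  representation(values = "matrix", xll = "numeric", yll = "numeric",
                 cellsize = "numeric", crs = "character", nodata = "numeric",
                 timeStep = "character")
)

setValidity("IsoscapeGrid", function(object) {
  msgs <- character()
  if (object@cellsize <= 0) msgs <- c(msgs, "cellsize must be positive")
  v <- object@values
  if (any(!is.na(v) & !is.finite(v)))
    msgs <- c(msgs, "unmasked cells must be finite")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "IsoscapeGrid", function(object) {
  v <- object@values
  cat(sprintf(
    "IsoscapeGrid [%s]: %d x %d cells @ %g, %d nodata\n  range %s permil, origin (%g, %g), crs '%s'\n",
    object@timeStep, nrow(v), ncol(v), object@cellsize, sum(is.na(v)),
    if (all(is.na(v))) "all-NA" else
      paste(signif(range(v, na.rm = TRUE), 4), collapse = " .. "),
    object@xll, object@yll, object@crs))
  invisible(object)
})

#' Georeferenced EVI composite stack
#'
#' A dated stack of co-registered EVI grids (one layer per 16-day composite)
#' on the same minimal georeferencing as [IsoscapeGrid-class].
#'
#' @slot data 3-d numeric array `[row, col, composite]`; row 1 northernmost.
#' @slot dates composite start dates, one per layer.
#' @slot xll,yll,cellsize,crs georeferencing as in [IsoscapeGrid-class].
#' @seealso [simulateRasterStack()], [readEviStack()], [pixelSeries()]
#' @exportClass EviStack
setClass("EviStack",
  representation(data = "array", dates = "Date", xll = "numeric",
                 yll = "numeric", cellsize = "numeric", crs = "character")
)

setValidity("EviStack", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3-d array [row, col, composite]")
  else if (dim(object@data)[3] != length(object@dates))
    msgs <- c(msgs, "one composite date per layer is required")
  if (length(object@dates) >= 2L && any(diff(as.numeric(object@dates)) <= 0))
    msgs <- c(msgs, "composite dates must be strictly increasing")
  if (object@cellsize <= 0) msgs <- c(msgs, "cellsize must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EviStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EviStack: %d x %d pixels, %d composites (%s .. %s) @ %g, crs '%s'\n",
    d[1], d[2], d[3], min(object@dates), max(object@dates), object@cellsize,
    object@crs))
  invisible(object)
})

#' Extract one pixel's EVI time series from a stack
#'
#' @param stack an [EviStack-class].
#' @param row,col pixel indices (row 1 is the northernmost row).
#' @return an [EviSeries-class] for that pixel, siteId `"r<row>c<col>"`.
#' @export
pixelSeries <- function(stack, row, col) {
  stopifnot(is(stack, "EviStack"))
  d <- dim(stack@data)
  if (row < 1 || row > d[1] || col < 1 || col > d[2])
    stop(sprintf("pixel (%d, %d) outside the %d x %d grid", row, col,
                 d[1], d[2]))
  EviSeries(values = stack@data[row, col, ], dates = stack@dates,
            siteId = sprintf("r%dc%d", row, col))
}
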
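.requireCols <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  df
}

#' Read a precipitation-sampling observation table
#'
#' Expected CSV layout: one row per sampling interval with columns
#' `site_id, start, end` (ISO-8601 dates), `d18o` (per-mil) and optionally
#' `dD`, `amount` and `elevation`.
#'
#' @param path CSV file.
#' @return a data.frame with parsed `Date` columns; bad rows raise an error
#'   naming the row number.
#' @export
readStationObs <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, c("site_id", "start", "end", "d18o"), path)
  for (cn in c("start", "end")) {
    d <- as.Date(df[[cn]], format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(df[[cn]]))
    if (length(bad))
      stop(sprintf("%s: unparseable %s date at row %d", path, cn, bad[1L]))
    df[[cn]] <- d
  }
  bad <- which(!is.finite(df$d18o))
  if (length(bad))
    stop(sprintf("%s: non-finite d18o at row %d", path, bad[1L]))
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(sprintf("%s: interval end precedes start at row %d", path, bad[1L]))
  df
}

#' Read / write per-site EVI composite series
#'
#' CSV layout: columns `site_id, date` (ISO-8601 composite start date) and
#' `evi`, one row per composite.
#'
#' @param path CSV file.
#' @return `readEviSeries`: a named list of [EviSeries-class], one per site.
#' @export
readEviSeries <- function(path) {
  if (!file.exists(path)) stop("EVI file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, c("site_id", "date", "evi"), path)
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d)) stop(sprintf("%s: unparseable date at row %d", path,
                             which(is.na(d))[1L]))
  df$date <- d
  lapply(split(df, df$site_id), function(sdf) {
    sdf <- sdf[order(sdf$date), , drop = FALSE]
    EviSeries(values = sdf$evi, dates = sdf$date, siteId = sdf$site_id[1L])
  })
}

#' @describeIn readEviSeries write a list of series (raw values; the
#'   smoothed curve is written as an extra `smoothed` column when present).
#' @param seriesList named list of [EviSeries-class].
#' @export
writeEviSeries <- function(seriesList, path) {
  rows <- lapply(seriesList, function(s) {
    if (!length(s@dates))
      stop("series '", s@siteId, "' has no composite dates; cannot serialise")
    df <- data.frame(site_id = s@siteId, date = format(s@dates, "%Y-%m-%d"),
                     evi = s@values, stringsAsFactors = FALSE)
    if (length(s@smoothed)) df$smoothed <- s@smoothed
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a site-constants table
#'
#' CSV mirror of the published constants layout: columns
#' `station, a, b, c, d, e`, plus any extra columns (e.g. `elevation`,
#' `model_ievi`) which are carried through unchanged.
#'
#' @param path CSV file.
#' @return `readConstants`: the data.frame, each row validated against the
#'   parameter feasibility bounds.
#' @export
readConstants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, c("station", "a", "b", "c", "d", "e"), path)
  for (i in seq_len(nrow(df)))
    .rowToParams(df[i, ])        # validity check, errors on bad rows
  df
}

#' @describeIn readConstants write a constants table.
#' @param constants data.frame with at least `station, a, b, c, d, e`.
#' @export
writeConstants <- function(constants, path) {
  .requireCols(constants, c("station", "a", "b", "c", "d", "e"), "constants")
  utils::write.csv(constants, path, row.names = FALSE)
  invisible(path)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster with the standard 6-line header
#' (`ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value`); row 1 of
#' the matrix is written first (northernmost row), matching the format's
#' top-down order. CRS and any time-step label travel in an optional JSON
#' sidecar `<path>.aux.json`.
#'
#' @param x an [IsoscapeGrid-class], or a numeric matrix.
#' @param path output `.asc` file.
#' @param xll,yll,cellsize,nodata,crs georeferencing (matrix method only;
#'   the grid method takes them from the object).
#' @param timeStep optional label stored in the sidecar.
#' @return the path, invisibly.
#' @export
setGeneric("writeAsciiGrid",
           function(x, path, ...) standardGeneric("writeAsciiGrid"))

.writeAsc <- function(values, path, xll, yll, cellsize, nodata, crs,
                      timeStep) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(values)),
               sprintf("nrows %d", nrow(values)),
               sprintf("xllcorner %.10g", xll),
               sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.10g", cellsize),
               sprintf("NODATA_value %.10g", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(crs = crs, time_step = timeStep),
                       paste0(path, ".aux.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
setMethod("writeAsciiGrid", "IsoscapeGrid", function(x, path, ...) {
  .writeAsc(x@values, path, x@xll, x@yll, x@cellsize, x@nodata, x@crs,
            x@timeStep)
})

#' @rdname writeAsciiGrid
#' @export
setMethod("writeAsciiGrid", "matrix",
  function(x, path, xll = 0, yll = 0, cellsize = 250, nodata = -9999,
           crs = "", timeStep = "") {
    .writeAsc(x, path, xll, yll, cellsize, nodata, crs, timeStep)
  })

#' Read an ESRI ASCII raster
#'
#' @param path `.asc` file written by [writeAsciiGrid()] (or any conforming
#'   file); a `<path>.aux.json` sidecar, when present, restores CRS and
#'   time-step metadata.
#' @return an [IsoscapeGrid-class] (nodata cells as `NA`).
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop(path, ": not an ESRI ASCII grid (missing georeferencing header)")
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  if (nrow(m) != vals[["nrows"]] || ncol(m) != vals[["ncols"]])
    stop(path, ": grid dimensions do not match the header")
  m[m == vals[["nodata_value"]]] <- NA_real_
  aux <- paste0(path, ".aux.json")
  meta <- if (file.exists(aux)) jsonlite::read_json(aux) else list()
  new("IsoscapeGrid", values = m, xll = vals[["xllcorner"]],
      yll = vals[["yllcorner"]], cellsize = vals[["cellsize"]],
      crs = if (is.null(meta$crs)) "" else meta$crs,
      nodata = vals[["nodata_value"]],
      timeStep = if (is.null(meta$time_step)) "" else meta$time_step)
}

#' Write / read an EVI composite stack as a directory of ASCII grids
#'
#' One ESRI ASCII grid per composite (`band_<date>.asc`) plus an
#' `index.json` listing the band files, their composite start dates and the
#' CRS. All bands must share the grid; a mismatch on read is an error.
#'
#' @param stack an [EviStack-class].
#' @param dir directory to create/read.
#' @return `writeEviStack`: `dir` invisibly; `readEviStack`: an
#'   [EviStack-class].
#' @export
writeEviStack <- function(stack, dir) {
  stopifnot(is(stack, "EviStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("band_%s.asc", format(stack@dates, "%Y-%m-%d"))
  for (k in seq_along(files))
    .writeAsc(stack@data[, , k], file.path(dir, files[k]), stack@xll,
              stack@yll, stack@cellsize, -9999, stack@crs, "")
  jsonlite::write_json(
    list(bands = files, dates = format(stack@dates, "%Y-%m-%d"),
         crs = stack@crs),
    file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeEviStack
#' @export
readEviStack <- function(dir) {
  idx <- file.path(dir, "index.json")
  if (!file.exists(idx)) stop("no index.json in ", dir)
  meta <- jsonlite::read_json(idx, simplifyVector = TRUE)
  if (is.null(meta$dates) || !length(meta$dates))
    stop(dir, ": stack index carries no composite dates")
  grids <- lapply(file.path(dir, meta$bands), readAsciiGrid)
  ref <- grids[[1L]]
  for (g in grids[-1L])
    if (g@xll != ref@xll || g@yll != ref@yll ||
        g@cellsize != ref@cellsize || !all(dim(g@values) == dim(ref@values)))
      stop(dir, ": bands are not co-registered (georeferencing differs)")
  data <- array(NA_real_,
                dim = c(nrow(ref@values), ncol(ref@values), length(grids)))
  for (k in seq_along(grids)) data[, , k] <- grids[[k]]@values
  new("EviStack", data = data, dates = as.Date(meta$dates), xll = ref@xll,
      yll = ref@yll, cellsize = ref@cellsize,
      crs = if (is.null(meta$crs)) ref@crs else meta$crs)
}

## ---- run configuration -----------------------------------------------------

.defaultRunConfig <- function() {
  list(
    seed = 1L,
    smoothing = list(window = 5L, polyDegree = 2L, envelopeIterations = 3L,
                     adaptationStrength = 3),
    season = list(threshold = 0.167, startFraction = 1 / 6,
                  minAmplitude = 0.02),
    fit = list(restarts = 30L, aCap = 0.01,
               aFloorGrid = seq(0.0005, 0.0035, by = 0.0005),
               dMinGrid = c(-0.1, -0.2, -0.3),
               dMaxGrid = c(0.1, 0.2, 0.3)),
    exclusion = list(zThreshold = 3),
    crs = "MODIS sinusoidal")
}

#' Assemble, write and read a run configuration
#'
#' A single human-readable YAML file holding every tunable of the pipeline
#' (smoothing, season definition, fit grids/restarts, extrema exclusion,
#' CRS, master seed). Unknown keys are rejected; a write/read round trip
#' returns the same configuration.
#'
#' @param ... overrides of the defaults, e.g. `seed = 42`,
#'   `smoothing = list(window = 4)` (partial sub-lists are merged).
#' @return the resolved configuration list, class `"RunConfig"`.
#' @export
runConfig <- function(...) {
  cfg <- .defaultRunConfig()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      sub <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(sub))
        stop(sprintf("unknown key(s) under '%s': %s", nm,
                     paste(sub, collapse = ", ")))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @param cfg a `"RunConfig"` list.
#' @param path YAML file.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(runConfig, raw)
}
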
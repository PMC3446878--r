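#' Reference site constants for a 13-station elevation gradient
#'
#' The published constants of the iEVI-d18O function for thirteen
#' precipitation-collection stations (s1..s13) ordered along a 91-2876 m
#' elevation gradient in the mountains of central Taiwan. They serve as the
#' default parameter gradient of the synthetic study-system generator and as
#' the ground truth of the parameter-recovery checks.
#'
#' @return a data.frame with columns `station, a, b, c, d, e`, one row per
#'   station from the lowest (s1) to the highest (s13) site.
#' @seealso [simulateStationNetwork()], [isoParams()]
#' @export
referenceConstants <- function() {
  data.frame(
    station = paste0("s", 1:13),
    a = c(0.003001, 0.003, 0.003, 0.003015, 0.001594, 0.002052, 0.002,
          0.002079, 0.003, 0.002425, 0.003719, 0.003012, 0.004665),
    b = c(110.655, 121.534, 118.662, 103.596, 129.2, 128.926, 102.816,
          110.508, 102.438, 101.434, 85.6215, 83.0063, 71.4633),
    c = c(-74.069, -79.0814, -80.6478, -83.0334, -107.567, -94.7936,
          -107.441, -94.6267, -84.1505, -78.0701, -62.2407, -67.4471,
          -54.9761),
    d = c(-0.00393, -0.00713, -0.00697, 0.01662, 0.005059, -0.00276,
          0.01834, -0.00237, 0.000375, 0.008645, -0.00175, 0.020753,
          0.027233),
    e = c(2.66119, 2.65982, 3.63887, 3.71285, 4.44664, 4.91114, 4.19058,
          5.8392, 6.07942, 6.52685, 6.66702, 7.81705, 8.55642),
    stringsAsFactors = FALSE
  )
}

## One row of a constants table -> IsoModelParams
.rowToParams <- function(row) {
  isoParams(row[["a"]], row[["b"]], row[["c"]], row[["d"]], row[["e"]])
}
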
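#' @import methods
NULL

## Central S4 containers. Grid cells are indexed 1..nRows*nCols in row-major
## order: cell = (row - 1) * nCols + col. All coordinates are projected km
## from the domain origin (lower-left corner).

#' Rectangular modeling domain with air-quality regions
#'
#' A regular grid of square cells, each assigned to exactly one air-quality
#' region. Cell centers are at ((col - 0.5), (row - 0.5)) times the cell size.
#'
#' @slot nRows,nCols grid dimensions.
#' @slot cellSizeKm edge length of a cell in km.
#' @slot regionId integer region code per cell (row-major), indexing
#'   \code{regionNames}.
#' @slot regionNames names of the configured regions.
#' @export
setClass("GridDomain",
  representation(nRows = "integer", nCols = "integer", cellSizeKm = "numeric",
                 regionId = "integer", regionNames = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "nRows and nCols must be >= 1")
    n <- object@nRows * object@nCols
    if (length(object@regionId) != n)
      msg <- c(msg, sprintf("regionId must have one entry per cell (%d)", n))
    if (length(object@regionNames) < 1L)
      msg <- c(msg, "region set must be non-empty")
    if (anyNA(object@regionId) ||
        any(object@regionId < 1L | object@regionId > length(object@regionNames)))
      msg <- c(msg, "every cell must carry exactly one valid region label")
    if (object@cellSizeKm <= 0) msg <- c(msg, "cellSizeKm must be positive")
    if (length(msg)) msg else TRUE
  })

#' Gridded cell-by-day pollutant concentrations
#'
#' Holds the concentration symbol C of the bias equations: raw CTM output,
#' fused scenario output, truth, or observation-derived exposure. Units are
#' ug/m3 for \code{pm25} (daily mean) and ppb for \code{o3} (MDA8).
#'
#' @slot pollutant \code{"pm25"} or \code{"o3"}.
#' @slot values numeric cell x day matrix; \code{NA} marks missing; non-missing
#'   entries are non-negative.
#' @slot days strictly increasing \code{Date} vector, one per column.
#' @slot domain the \linkS4class{GridDomain} the rows refer to.
#' @export
setClass("ConcentrationField",
  representation(pollutant = "character", values = "matrix", days = "Date",
                 domain = "GridDomain"),
  validity = function(object) {
    msg <- character()
    if (!object@pollutant %in% c("pm25", "o3"))
      msg <- c(msg, "pollutant must be 'pm25' or 'o3'")
    if (nrow(object@values) != nCells(object@domain))
      msg <- c(msg, "values must have one row per domain cell")
    if (ncol(object@values) != length(object@days))
      msg <- c(msg, "values must have one column per day")
    if (length(object@days) > 1L && any(diff(object@days) <= 0))
      msg <- c(msg, "day axis must be strictly increasing")
    v <- object@values
    if (any(v[!is.na(v)] < 0))
      msg <- c(msg, "non-missing concentrations must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Monitoring-station network with hourly series
#'
#' @slot stations data.frame with columns \code{stationId}, \code{x_km},
#'   \code{y_km}, \code{hostCell} (the in-domain cell containing the station).
#' @slot hourly long data.frame of hourly measurements with columns
#'   \code{stationId}, \code{time} (POSIXct, UTC, on-the-hour),
#'   \code{pollutant}, \code{value}; may be empty.
#' @slot domain the \linkS4class{GridDomain} stations live on.
#' @export
setClass("StationNetwork",
  representation(stations = "data.frame", hourly = "data.frame",
                 domain = "GridDomain"),
  validity = function(object) {
    msg <- character()
    st <- object@stations
    need <- c("stationId", "x_km", "y_km", "hostCell")
    if (!all(need %in% names(st)))
      return(sprintf("stations must have columns %s", paste(need, collapse = ", ")))
    if (anyDuplicated(st$stationId))
      msg <- c(msg, "station ids must be unique")
    n <- nCells(object@domain)
    if (nrow(st) && (anyNA(st$hostCell) || any(st$hostCell < 1L | st$hostCell > n)))
      msg <- c(msg, "every station must map to exactly one in-domain cell")
    if (nrow(object@hourly) &&
        !all(c("stationId", "time", "pollutant", "value") %in% names(object@hourly)))
      msg <- c(msg, "hourly must have columns stationId, time, pollutant, value")
    if (length(msg)) msg else TRUE
  })

#' Per-cell population and urbanization class
#'
#' Urbanization classes are coded 0 = rural, 1 = suburban, 2 = urban; the
#' class drives the stratified ("heterogeneous") exposure-risk coefficients.
#'
#' @slot population non-negative person count per cell.
#' @slot urbanClass integer in \{0, 1, 2\} per cell (\code{NA} allowed only
#'   where population is zero).
#' @export
setClass("PopulationGrid",
  representation(population = "numeric", urbanClass = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@population) != length(object@urbanClass))
      msg <- c(msg, "population and urbanClass must have equal length")
    if (any(object@population < 0, na.rm = TRUE))
      msg <- c(msg, "population must be >= 0")
    bad <- object@population > 0 & (is.na(object@urbanClass) |
                                    !object@urbanClass %in% 0:2)
    if (any(bad))
      msg <- c(msg, "every populated cell needs an urbanClass in {0,1,2}")
    if (length(msg)) msg else TRUE
  })

#' Raw and scenario-fused concentration fields
#'
#' Bundles the raw CTM field with the fused fields of the five training
#' scenarios: S1 (all predictor blocks), S2 (emissions only), S3 (boundary
#' conditions only), S4 (meteorology only), S5 (land use only). All fields
#' share one grid and day axis.
#'
#' @slot cmaq raw CTM \linkS4class{ConcentrationField}.
#' @slot fused named list of fused fields; names from
#'   \code{c("S1","S2","S3","S4","S5")}, \code{"S1"} required for bias work.
#' @export
setClass("ScenarioConcentrations",
  representation(cmaq = "ConcentrationField", fused = "list"),
  validity = function(object) {
    msg <- character()
    ok <- names(object@fused) %in% c("S1", "S2", "S3", "S4", "S5")
    if (length(object@fused) && (is.null(names(object@fused)) || !all(ok)))
      msg <- c(msg, "fused field names must be among S1..S5")
    for (f in object@fused) {
      if (!is(f, "ConcentrationField")) {
        msg <- c(msg, "fused entries must be ConcentrationField objects"); break
      }
      if (!identical(dim(f@values), dim(object@cmaq@values)) ||
          !identical(f@days, object@cmaq@days)) {
        msg <- c(msg, "all fields must share the grid and day axes"); break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Concentration-response function parameters
#'
#' Parameters of the threshold-exponential premature-death model
#' \deqn{Y = E_0 \cdot P \cdot (1 - e^{-\beta (C - C_0)}) \cdot A}
#' applied per cell-day with \eqn{(C - C_0)} clamped at zero below threshold.
#'
#' @slot pollutant pollutant the parameters refer to (units of \code{c0}).
#' @slot e0 baseline mortality rate, deaths per person per year.
#' @slot beta excess-risk coefficient per unit concentration; either a single
#'   averaged value (named \code{"avg"}) or one per urbanization class (named
#'   \code{"rural"}, \code{"suburban"}, \code{"urban"}).
#' @slot c0 threshold concentration (25 ug/m3 daily PM2.5, 60 ppb MDA8 O3).
#' @slot a day-to-year scalar, 1/365.
#' @export
setClass("CRFParams",
  representation(pollutant = "character", e0 = "numeric", beta = "numeric",
                 c0 = "numeric", a = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@e0 <= 0 || object@a <= 0) msg <- c(msg, "e0 and a must be > 0")
    if (any(object@beta < 0)) msg <- c(msg, "beta must be >= 0")
    if (object@c0 < 0) msg <- c(msg, "c0 must be >= 0")
    if (!length(object@beta) %in% c(1L, 3L))
      msg <- c(msg, "beta must be a single value or one per urbanization class")
    if (length(object@beta) == 3L &&
        !all(c("rural", "suburban", "urban") %in% names(object@beta)))
      msg <- c(msg, "stratified beta needs names rural, suburban, urban")
    if (length(msg)) msg else TRUE
  })
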
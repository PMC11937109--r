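#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GridDomain
#'
#' @param nRows,nCols grid dimensions.
#' @param cellSizeKm cell edge length in km (default 3, a typical inner-nest
#'   CTM resolution).
#' @param regionId integer region code per cell in row-major order; defaults
#'   to a single region covering the whole domain.
#' @param regionNames names of the regions; defaults to \code{"R1"}, ...
#' @return A \linkS4class{GridDomain}.
#' @examples
#' gridDomain(2, 3, 3)
#' @export
gridDomain <- function(nRows, nCols, cellSizeKm = 3,
                       regionId = rep(1L, nRows * nCols),
                       regionNames = paste0("R", seq_len(max(regionId)))) {
  new("GridDomain", nRows = as.integer(nRows), nCols = as.integer(nCols),
      cellSizeKm = as.numeric(cellSizeKm), regionId = as.integer(regionId),
      regionNames = as.character(regionNames))
}

#' Construct a ConcentrationField
#'
#' @param pollutant \code{"pm25"} or \code{"o3"}.
#' @param values numeric cell x day matrix (or vector recyclable to one).
#' @param days \code{Date} vector, one per column.
#' @param domain the \linkS4class{GridDomain}.
#' @return A \linkS4class{ConcentrationField}.
#' @export
concentrationField <- function(pollutant, values, days, domain) {
  days <- as.Date(days)
  if (!is.matrix(values))
    values <- matrix(values, nrow = nCells(domain), ncol = length(days))
  new("ConcentrationField", pollutant = pollutant, values = values,
      days = days, domain = domain)
}

#' Construct a StationNetwork
#'
#' Stations are collocated with their host cell from projected coordinates;
#' off-grid stations are an error.
#'
#' @param stations data.frame with columns \code{stationId}, \code{x_km},
#'   \code{y_km} (and optionally a precomputed \code{hostCell}).
#' @param domain the \linkS4class{GridDomain}.
#' @param hourly optional long data.frame of hourly measurements
#'   (\code{stationId}, \code{time}, \code{pollutant}, \code{value}).
#' @return A \linkS4class{StationNetwork}.
#' @export
stationNetwork <- function(stations, domain, hourly = emptyHourly()) {
  stations <- as.data.frame(stations)
  if (is.null(stations$hostCell))
    stations$hostCell <- hostCell(stations$x_km, stations$y_km, domain)
  stations$stationId <- as.character(stations$stationId)
  stations <- stations[order(stations$stationId), , drop = FALSE]
  rownames(stations) <- NULL
  new("StationNetwork", stations = stations, hourly = as.data.frame(hourly),
      domain = domain)
}

emptyHourly <- function() {
  data.frame(stationId = character(), time = as.POSIXct(character(), tz = "UTC"),
             pollutant = character(), value = numeric())
}

#' Construct a PopulationGrid
#'
#' @param population non-negative per-cell person counts.
#' @param urbanClass integer per cell: 0 rural, 1 suburban, 2 urban.
#' @return A \linkS4class{PopulationGrid}.
#' @export
populationGrid <- function(population, urbanClass) {
  new("PopulationGrid", population = as.numeric(population),
      urbanClass = as.integer(urbanClass))
}

#' Construct a ScenarioConcentrations bundle
#'
#' @param cmaq raw CTM field.
#' @param fused named list of fused fields (\code{"S1"} ... \code{"S5"}).
#' @return A \linkS4class{ScenarioConcentrations}.
#' @export
scenarioConcentrations <- function(cmaq, fused) {
  new("ScenarioConcentrations", cmaq = cmaq, fused = fused)
}

## ---- accessors ----

#' @describeIn nCells cell count of a domain
#' @export
setMethod("nCells", "GridDomain", function(x) x@nRows * x@nCols)

#' @describeIn cellCenters centers of a domain's cells
#' @export
setMethod("cellCenters", "GridDomain", function(x) {
  idx <- seq_len(nCells(x)) - 1L
  row <- idx %/% x@nCols + 1L
  col <- idx %% x@nCols + 1L
  cbind(x_km = (col - 0.5) * x@cellSizeKm, y_km = (row - 0.5) * x@cellSizeKm)
})

#' @describeIn regionIds region name per cell
#' @export
setMethod("regionIds", "GridDomain", function(x) x@regionNames[x@regionId])

#' @describeIn concValues the raw matrix
#' @export
setMethod("concValues", "ConcentrationField", function(x) x@values)

#' @describeIn fieldDays the day axis
#' @export
setMethod("fieldDays", "ConcentrationField", function(x) x@days)

#' @describeIn pollutant the pollutant code
#' @export
setMethod("pollutant", "ConcentrationField", function(x) x@pollutant)

#' Measurement units for a pollutant
#'
#' @param pollutant \code{"pm25"} or \code{"o3"}.
#' @return \code{"ug/m3"} or \code{"ppb"}.
#' @export
pollutantUnits <- function(pollutant) {
  switch(pollutant, pm25 = "ug/m3", o3 = "ppb",
         stop("unknown pollutant: ", pollutant))
}

setMethod("show", "GridDomain", function(object) {
  cat(sprintf("GridDomain: %d x %d cells of %g km, %d regions (%s)\n",
              object@nRows, object@nCols, object@cellSizeKm,
              length(object@regionNames),
              paste(object@regionNames, collapse = ", ")))
})

setMethod("show", "ConcentrationField", function(object) {
  v <- object@values
  cat(sprintf("ConcentrationField: %s [%s], %d cells x %d days (%s .. %s)\n",
              object@pollutant, pollutantUnits(object@pollutant),
              nrow(v), ncol(v), min(object@days), max(object@days)))
  cat(sprintf("  mean %.2f, range [%.2f, %.2f], %d missing\n",
              mean(v, na.rm = TRUE), suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "StationNetwork", function(object) {
  cat(sprintf("StationNetwork: %d stations, %d hourly records\n",
              nrow(object@stations), nrow(object@hourly)))
})

setMethod("show", "ScenarioConcentrations", function(object) {
  cat(sprintf("ScenarioConcentrations (%s): CMAQ + fused %s\n",
              object@cmaq@pollutant,
              paste(names(object@fused), collapse = ", ")))
})

## ---- spatial utilities ----

#' Map projected coordinates to host cells
#'
#' @param x,y coordinates in km from the domain origin.
#' @param domain a \linkS4class{GridDomain}.
#' @return Integer cell indices (row-major). Off-grid points are an error.
#' @export
hostCell <- function(x, y, domain) {
  col <- pmin(pmax(ceiling(x / domain@cellSizeKm), 1L), domain@nCols)
  row <- pmin(pmax(ceiling(y / domain@cellSizeKm), 1L), domain@nRows)
  off <- x < 0 | y < 0 | x > domain@nCols * domain@cellSizeKm |
         y > domain@nRows * domain@cellSizeKm
  if (any(off)) stop("station coordinates fall outside the domain")
  as.integer((row - 1L) * domain@nCols + col)
}

#' Nearest monitoring station to a grid cell
#'
#' Finds the station minimizing the Euclidean distance between the cell
#' center and the station location. Ties are broken by the lexicographically
#' smallest station id, so the assignment is deterministic.
#'
#' @param cell cell index (row-major) in the network's domain.
#' @param net a \linkS4class{StationNetwork}.
#' @return The station id (character scalar).
#' @export
nearestStation <- function(cell, net) {
  st <- net@stations
  if (nrow(st) == 0L) stop("station network is empty")
  n <- nCells(net@domain)
  if (any(cell < 1L | cell > n)) stop("cell index outside the domain")
  ctr <- cellCenters(net@domain)[cell, , drop = FALSE]
  vapply(seq_len(nrow(ctr)), function(i) {
    d <- sqrt((st$x_km - ctr[i, 1])^2 + (st$y_km - ctr[i, 2])^2)
    cand <- which(d <= min(d) + 1e-12)
    sid <- st$stationId[cand]
    sort(sid)[1L]
  }, character(1))
}

#' @describeIn populationWeightedMean population-weighted mean of a field
#' @export
setMethod("populationWeightedMean",
          signature(field = "ConcentrationField", pop = "PopulationGrid"),
  function(field, pop, region = "all", day = "all") {
    dom <- field@domain
    inScope <- if (identical(region, "all")) rep(TRUE, nCells(dom))
               else regionIds(dom) == region
    if (!any(inScope)) stop("unknown region: ", region)
    cols <- if (identical(day, "all")) seq_along(field@days)
            else match(as.Date(day), field@days)
    if (anyNA(cols)) stop("day not on the field's axis")
    P <- pop@population[inScope]
    V <- field@values[inScope, cols, drop = FALSE]
    perDay <- vapply(seq_len(ncol(V)), function(j) {
      ok <- !is.na(V[, j])
      tot <- sum(P[ok])
      if (tot <= 0) stop("population in scope is zero; weighting undefined")
      sum(P[ok] * V[ok, j]) / tot
    }, numeric(1))
    mean(perDay)
  })
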
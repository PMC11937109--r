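#' @include AllClasses.R
NULL

#' Number of grid cells
#'
#' @param x a \linkS4class{GridDomain} or an object carrying one.
#' @return Integer cell count.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Cell center coordinates
#'
#' @param x a \linkS4class{GridDomain}.
#' @return A two-column matrix (\code{x_km}, \code{y_km}) of cell centers in
#'   kilometers from the domain origin, one row per cell in row-major order.
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' Per-cell region labels
#'
#' @param x a \linkS4class{GridDomain}.
#' @return Character vector of region names, one per cell.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' Concentration matrix
#'
#' @param x a \linkS4class{ConcentrationField}.
#' @return Numeric cell-by-day matrix (may contain \code{NA}).
#' @export
setGeneric("concValues", function(x) standardGeneric("concValues"))

#' Day axis of a field
#'
#' @param x a \linkS4class{ConcentrationField}.
#' @return Vector of \code{Date}s, strictly increasing.
#' @export
setGeneric("fieldDays", function(x) standardGeneric("fieldDays"))

#' Pollutant identity
#'
#' @param x a \linkS4class{ConcentrationField}.
#' @return \code{"pm25"} or \code{"o3"}.
#' @export
setGeneric("pollutant", function(x) standardGeneric("pollutant"))

#' Population-weighted mean concentration
#'
#' Computes \eqn{\sum_c P_c C_c / \sum_c P_c} over the cells in scope,
#' excluding cells whose concentration is missing from both sums. This is the
#' exposure-relevant aggregate used throughout bias quantification: it weights
#' concentration by where people live rather than by area.
#'
#' @param field a \linkS4class{ConcentrationField}.
#' @param pop a \linkS4class{PopulationGrid} on the same domain.
#' @param region a region name restricting the scope, or \code{"all"}.
#' @param day a \code{Date} (or day index) selecting one day, or \code{"all"}
#'   for the mean over days of the per-day weighted means.
#' @return A single numeric value.
#' @examples
#' dom <- gridDomain(1, 2, 3)
#' f <- concentrationField("pm25", matrix(c(10, 20), 2, 1), as.Date("2016-01-01"), dom)
#' p <- populationGrid(c(1, 3), c(0L, 2L))
#' populationWeightedMean(f, p)  # (1*10 + 3*20) / 4 = 17.5
#' @export
setGeneric("populationWeightedMean",
           function(field, pop, region = "all", day = "all")
             standardGeneric("populationWeightedMean"))
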
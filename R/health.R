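#' @include AllClasses.R domain.R metrics.R
NULL

## Burden-of-disease stage: threshold-exponential concentration-response
## deaths, exposure-source and risk-scheme sensitivity, improvement ratios.

#' Round half away from zero
#'
#' Integer-style rounding in which halves move away from zero (2.5 -> 3,
#' -2.5 -> -3), the convention used for all reported percentages.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct concentration-response parameters
#'
#' @param pollutant \code{"pm25"} or \code{"o3"}; fixes the default threshold
#'   (25 ug/m3 daily PM2.5, 60 ppb MDA8 O3).
#' @param e0 baseline mortality rate, deaths per person per year.
#' @param beta excess-risk coefficient per unit concentration: a single
#'   averaged value, or a named vector (\code{rural}, \code{suburban},
#'   \code{urban}) for the heterogeneous scheme.
#' @param c0 threshold concentration (defaulted from the pollutant).
#' @param a day-to-year scalar, 1/365.
#' @return A \linkS4class{CRFParams}.
#' @export
crfParams <- function(pollutant = c("pm25", "o3"), e0, beta,
                      c0 = c(pm25 = 25, o3 = 60)[[pollutant]], a = 1 / 365) {
  pollutant <- match.arg(pollutant)
  new("CRFParams", pollutant = pollutant, e0 = e0, beta = beta, c0 = c0, a = a)
}

#' Default synthetic risk parameters
#'
#' Plausible defaults for the synthetic study: baseline mortality 0.007
#' deaths/person/year and urbanization-stratified risk coefficients whose
#' urban value is twice the rural one. The heterogeneous scheme uses the
#' stratified vector; the averaged scheme is derived with
#' \code{\link{averageRisk}}.
#'
#' @param pollutant \code{"pm25"} or \code{"o3"}.
#' @return A heterogeneous-risk \linkS4class{CRFParams}.
#' @export
defaultCRFParams <- function(pollutant = c("pm25", "o3")) {
  pollutant <- match.arg(pollutant)
  beta <- if (pollutant == "pm25")
    c(rural = 0.0008, suburban = 0.0012, urban = 0.0016)
  else c(rural = 0.0006, suburban = 0.0009, urban = 0.0012)
  crfParams(pollutant, e0 = 0.007, beta = beta)
}

#' Average-risk parameters from heterogeneous ones
#'
#' Collapses urbanization-stratified risk coefficients into a single value by
#' population-weighting the class coefficients, the homogeneous-risk
#' counterfactual of the sensitivity analysis.
#'
#' @param params a heterogeneous \linkS4class{CRFParams}.
#' @param pop the \linkS4class{PopulationGrid} supplying class weights.
#' @return A \linkS4class{CRFParams} with a single averaged \code{beta}.
#' @export
averageRisk <- function(params, pop) {
  if (length(params@beta) == 1L) return(params)
  cls <- c("rural", "suburban", "urban")[pop@urbanClass + 1L]
  w <- tapply(pop@population, factor(cls, levels = names(params@beta)), sum)
  w[is.na(w)] <- 0
  avg <- sum(params@beta * w) / sum(w)
  crfParams(params@pollutant, params@e0, c(avg = unname(avg)), params@c0,
            params@a)
}

cellBeta <- function(params, pop) {
  if (length(params@beta) == 1L) return(rep(params@beta, length(pop@population)))
  b <- params@beta[c("rural", "suburban", "urban")]
  out <- b[pop@urbanClass + 1L]
  out[is.na(out)] <- 0  # unclassified cells carry no population
  unname(out)
}

#' Premature deaths from a concentration field
#'
#' Evaluates, per cell-day, the threshold-exponential concentration-response
#' function \deqn{y = E_0 \cdot P \cdot (1 - e^{-\beta \max(C - C_0, 0)})
#' \cdot A} and sums over the days and the cells in scope. Under the
#' heterogeneous scheme \eqn{\beta} is taken from each cell's urbanization
#' class. Missing cell-days contribute nothing.
#'
#' @param field exposure \linkS4class{ConcentrationField}; its pollutant must
#'   match the parameters (units of the threshold).
#' @param pop a \linkS4class{PopulationGrid}.
#' @param params a \linkS4class{CRFParams}.
#' @param scope region name or \code{"all"}.
#' @return Total premature deaths (numeric scalar).
#' @examples
#' dom <- gridDomain(1, 1)
#' f <- concentrationField("pm25", matrix(35), as.Date("2016-01-01"), dom)
#' p <- populationGrid(1000, 2L)
#' crfDeaths(f, p, crfParams("pm25", e0 = 365, beta = 0.001))
#' # 1000 * (1 - exp(-0.01)) = 9.95
#' @export
crfDeaths <- function(field, pop, params, scope = "all") {
  if (field@pollutant != params@pollutant)
    stop("exposure units do not match the CRF threshold: field is ",
         field@pollutant, ", params are ", params@pollutant)
  dom <- field@domain
  inScope <- if (identical(scope, "all")) rep(TRUE, nCells(dom))
             else regionIds(dom) == scope
  if (!any(inScope)) stop("unknown region: ", scope)
  P <- pop@population[inScope]
  beta <- cellBeta(params, pop)[inScope]
  C <- field@values[inScope, , drop = FALSE]
  excess <- pmax(C - params@c0, 0)
  y <- params@e0 * P * (1 - exp(-beta * excess)) * params@a
  sum(y, na.rm = TRUE)
}

#' Observation-derived exposure field
#'
#' Assigns to every cell-day the daily metric of its nearest monitoring
#' station (Euclidean distance between cell center and station, lexicographic
#' tie-break). Missing station-days propagate as missing cell-days.
#'
#' @param metrics station daily metrics from
#'   \code{\link{stationDailyMetrics}}.
#' @param net the \linkS4class{StationNetwork}.
#' @param pollutant \code{"pm25"} or \code{"o3"}.
#' @return A \linkS4class{ConcentrationField} over the network's domain.
#' @export
exposureFromObservations <- function(metrics, net, pollutant = c("pm25", "o3")) {
  pollutant <- match.arg(pollutant)
  if (nrow(net@stations) == 0L) stop("station network is empty")
  dom <- net@domain
  days <- sort(unique(metrics$day))
  near <- nearestStation(seq_len(nCells(dom)), net)
  m <- matrix(NA_real_, nrow(net@stations), length(days),
              dimnames = list(net@stations$stationId, as.character(days)))
  m[cbind(match(metrics$stationId, rownames(m)), match(metrics$day, days))] <-
    metrics$value
  vals <- m[match(near, rownames(m)), , drop = FALSE]
  concentrationField(pollutant, unname(vals), days, dom)
}

#' Improvement ratio of a single-block scenario
#'
#' Fraction of the CTM-vs-fused death-estimate discrepancy removed by the
#' scenario: \deqn{IR = (1 - |Y_s - Y_{S1}| / |Y_{CMAQ} - Y_{S1}|) \times
#' 100} 100 percent means the scenario reproduces the fully fused (S1)
#' estimate; 0 percent means it is no better than the raw CTM.
#'
#' @param yScenario deaths under the scenario (S2-S5).
#' @param yS1 deaths under the fully fused baseline.
#' @param yCmaq deaths under the raw CTM field.
#' @param rounded report the integer percent (half away from zero)? Default
#'   \code{TRUE}; \code{FALSE} returns the unrounded value.
#' @return Percent (vectorized over \code{yScenario}).
#' @examples
#' improvementRatio(7374, 7454, 13331)  # 99
#' @export
improvementRatio <- function(yScenario, yS1, yCmaq, rounded = TRUE) {
  if (any(yCmaq == yS1))
    stop("improvement ratio undefined: CTM and fused deaths coincide")
  ir <- (1 - abs(yScenario - yS1) / abs(yCmaq - yS1)) * 100
  if (rounded) roundHalfUp(ir) else ir
}

#' Relative bias of one death estimate against a reference
#'
#' \eqn{(Y_{alt} - Y_{ref}) / Y_{ref} \times 100}.
#'
#' @param yAlt alternative estimate.
#' @param yRef reference estimate (> 0).
#' @param rounded report the integer percent? Default \code{TRUE}.
#' @return Percent (vectorized).
#' @examples
#' biasPercent(10218, 7454)  # 37
#' @export
biasPercent <- function(yAlt, yRef, rounded = TRUE) {
  if (any(yRef <= 0)) stop("reference deaths must be positive")
  b <- (yAlt - yRef) / yRef * 100
  if (rounded) roundHalfUp(b) else b
}

#' Deaths and improvement ratios by exposure source
#'
#' Tabulates premature deaths per region (and the domain total) for the
#' observation-derived field, the raw CTM field and each fused scenario, with
#' the improvement ratio of every single-block scenario.
#'
#' @param sc a \linkS4class{ScenarioConcentrations}.
#' @param obsField observation-derived exposure from
#'   \code{\link{exposureFromObservations}}.
#' @param pop a \linkS4class{PopulationGrid}.
#' @param params a \linkS4class{CRFParams}.
#' @return data.frame with columns \code{region}, \code{source},
#'   \code{deaths}, \code{ir} (\code{NA} outside S2-S5) and \code{irRaw}.
#' @export
scenarioDeathsTable <- function(sc, obsField, pop, params) {
  fields <- c(list(observation = obsField, cmaq = sc@cmaq), sc@fused)
  regions <- c(sc@cmaq@domain@regionNames, "Total")
  rows <- lapply(regions, function(r) {
    scope <- if (r == "Total") "all" else r
    y <- vapply(fields, crfDeaths, numeric(1), pop = pop, params = params,
                scope = scope)
    d <- data.frame(region = r, source = names(fields), deaths = unname(y))
    sCols <- intersect(c("S2", "S3", "S4", "S5"), names(fields))
    d$irRaw <- NA_real_
    if (length(sCols) && y[["cmaq"]] != y[["S1"]])
      d$irRaw[match(sCols, d$source)] <-
        improvementRatio(y[sCols], y[["S1"]], y[["cmaq"]], rounded = FALSE)
    d$ir <- ifelse(is.na(d$irRaw), NA_real_, roundHalfUp(d$irRaw))
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity of deaths to exposure source and risk scheme
#'
#' Crosses the exposure sources (observation-nearest, raw CTM, fused) with
#' the risk schemes (averaged vs urbanization-stratified) per region, and
#' reports each cell's bias percentage against the most ideal setting: the
#' fused field with heterogeneous risk.
#'
#' @param sources named list of exposure \linkS4class{ConcentrationField}s;
#'   must include \code{"mmf"} (the fused reference), typically also
#'   \code{"observation"} and \code{"cmaq"}.
#' @param pop a \linkS4class{PopulationGrid}.
#' @param paramsAvg,paramsHet averaged and heterogeneous
#'   \linkS4class{CRFParams}.
#' @return data.frame with columns \code{region}, \code{source},
#'   \code{scheme}, \code{deaths}, \code{biasPct} (integer percent vs
#'   fused/heterogeneous, \code{NA} for the reference itself).
#' @export
sensitivityMatrix <- function(sources, pop, paramsAvg, paramsHet) {
  if (!"mmf" %in% names(sources))
    stop("sources must include the fused reference field 'mmf'")
  dom <- sources$mmf@domain
  regions <- c(dom@regionNames, "Total")
  rows <- list()
  for (r in regions) {
    scope <- if (r == "Total") "all" else r
    for (s in names(sources)) for (sch in c("average", "heterogeneous")) {
      p <- if (sch == "average") paramsAvg else paramsHet
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, source = s, scheme = sch,
        deaths = crfDeaths(sources[[s]], pop, p, scope))
    }
  }
  out <- do.call(rbind, rows)
  ref <- out[out$source == "mmf" & out$scheme == "heterogeneous",
             c("region", "deaths")]
  refY <- ref$deaths[match(out$region, ref$region)]
  out$biasPct <- ifelse(out$source == "mmf" & out$scheme == "heterogeneous",
                        NA_real_,
                        ifelse(refY > 0, roundHalfUp((out$deaths - refY) / refY * 100),
                               NA_real_))
  rownames(out) <- NULL
  out
}
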
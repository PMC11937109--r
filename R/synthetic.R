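#' @include AllClasses.R domain.R
NULL

## The generator produces a complete synthetic study: predictor blocks, a
## latent truth concentration field, a CTM field whose error is a known
## function of each predictor block plus white noise, station observations,
## and a clustered population surface. Because every component bias surface
## is returned, downstream fusion/apportionment stages can be validated
## against exact ground truth.

#' Configuration of a synthetic study
#'
#' Defaults emulate the study conditions at desk scale: a regular 3-km grid
#' with six contiguous air-quality regions, four observation months
#' (January, April, July, October 2016) of daily values, stations placed
#' preferentially in populated cells, and CTM bias dominated by boundary
#' conditions, then meteorology, then emissions, then land use
#' (\code{gamma = c(em = 1, bc = 5, mt = 2, lu = 0.5)}).
#'
#' @slot seed master seed; fixes all outputs bit-identically. Separate RNG
#'   streams are derived per artifact so e.g. adding stations never perturbs
#'   the fields.
#' @slot nRows,nCols,cellSizeKm grid geometry.
#' @slot nStations number of monitoring stations (must be <= cell count).
#' @slot nRegions number of contiguous air-quality regions.
#' @slot year,months calendar scope; daily values over the listed months.
#' @slot daysPerMonth cap on days used per month (\code{NA} = full months).
#' @slot gamma named component bias gains (\code{em}, \code{bc}, \code{mt},
#'   \code{lu}), concentration units per unit of the transform f_k.
#' @slot gammaPollutantScale per-pollutant multiplier on \code{gamma}; the
#'   default gives O3 biases in ppb a larger magnitude than PM2.5 biases in
#'   ug/m3, as regional evaluations typically show.
#' @slot obsNoiseSd per-pollutant Gaussian sd of station observation error.
#' @slot ctmNoiseSd per-pollutant sd of the unexplained white CTM error.
#' @slot popClusters,popLogSd clustering of the log-normal population surface.
#' @export
setClass("SyntheticConfig",
  representation(seed = "integer", nRows = "integer", nCols = "integer",
                 cellSizeKm = "numeric", nStations = "integer",
                 nRegions = "integer", year = "integer", months = "integer",
                 daysPerMonth = "integer", gamma = "numeric",
                 gammaPollutantScale = "numeric", obsNoiseSd = "numeric",
                 ctmNoiseSd = "numeric", popClusters = "integer",
                 popLogSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nStations > object@nRows * object@nCols)
      msg <- c(msg, "nStations must not exceed the number of cells")
    if (any(object@obsNoiseSd < 0) || any(object@ctmNoiseSd < 0))
      msg <- c(msg, "noise sds must be >= 0")
    if (!all(c("em", "bc", "mt", "lu") %in% names(object@gamma)))
      msg <- c(msg, "gamma needs names em, bc, mt, lu")
    if (!all(c("pm25", "o3") %in% names(object@obsNoiseSd)) ||
        !all(c("pm25", "o3") %in% names(object@ctmNoiseSd)) ||
        !all(c("pm25", "o3") %in% names(object@gammaPollutantScale)))
      msg <- c(msg, "per-pollutant vectors need names pm25, o3")
    if (length(msg)) msg else TRUE
  })

#' @rdname SyntheticConfig-class
#' @param seed,nRows,nCols,cellSizeKm,nStations,nRegions,year,months,daysPerMonth,gamma,gammaPollutantScale,obsNoiseSd,ctmNoiseSd,popClusters,popLogSd see slots.
#' @return A \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(seed = 1L, nRows = 30L, nCols = 40L,
                            cellSizeKm = 3, nStations = 20L, nRegions = 6L,
                            year = 2016L, months = c(1L, 4L, 7L, 10L),
                            daysPerMonth = NA_integer_,
                            gamma = c(em = 1, bc = 5, mt = 2, lu = 0.5),
                            gammaPollutantScale = c(pm25 = 1, o3 = 1.8),
                            obsNoiseSd = c(pm25 = 1.5, o3 = 2),
                            ctmNoiseSd = c(pm25 = 1.2, o3 = 1.5),
                            popClusters = 5L, popLogSd = 0.6) {
  new("SyntheticConfig", seed = as.integer(seed), nRows = as.integer(nRows),
      nCols = as.integer(nCols), cellSizeKm = cellSizeKm,
      nStations = as.integer(nStations), nRegions = as.integer(nRegions),
      year = as.integer(year), months = as.integer(months),
      daysPerMonth = as.integer(daysPerMonth), gamma = gamma,
      gammaPollutantScale = gammaPollutantScale, obsNoiseSd = obsNoiseSd,
      ctmNoiseSd = ctmNoiseSd, popClusters = as.integer(popClusters),
      popLogSd = popLogSd)
}

#' Gridded predictor blocks
#'
#' The four CTM input blocks used as fusion predictors: precursor emissions
#' (EM: PM2.5, NOx, SOx, NH3, VOCs), boundary-condition inflow series (BC,
#' per day, broadcast across cells), meteorology proxies at two pressure
#' levels (MT: temperature and wind at 850 and 690 hPa analogues), and static
#' land use (LU: urban fraction, forest fraction, elevation).
#'
#' @slot em named list of cell x day matrices, one per precursor species.
#' @slot bc data.frame with one row per day (columns \code{bc_pm},
#'   \code{bc_o3}).
#' @slot mt named list of cell x day matrices.
#' @slot lu data.frame with one row per cell (static across days).
#' @slot days the day axis.
#' @slot domain the grid the blocks live on.
#' @export
setClass("PredictorBlocks",
  representation(em = "list", bc = "data.frame", mt = "list",
                 lu = "data.frame", days = "Date", domain = "GridDomain"),
  validity = function(object) {
    n <- nCells(object@domain); nd <- length(object@days)
    for (m in c(object@em, object@mt))
      if (!identical(dim(m), c(n, nd)))
        return("em/mt matrices must be cells x days")
    if (nrow(object@bc) != nd) return("bc must have one row per day")
    if (nrow(object@lu) != n) return("lu must have one row per cell")
    if (any(vapply(object@em, function(m) any(m < 0), logical(1))) ||
        any(object@lu < 0))
      return("em and lu must be non-negative")
    TRUE
  })

## distinct RNG stream per artifact, derived from the master seed
subSeed <- function(seed, k) as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483647)

ar1Series <- function(n, phi, sd) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd / sqrt(1 - phi^2))
  for (t in seq_len(n - 1L)) x[t + 1L] <- phi * x[t] + rnorm(1, 0, sd)
  x
}

## sum of random Gaussian bumps over the grid; returns a per-cell surface
smoothSurface <- function(domain, nBumps, widthFrac = 0.2, ampSd = 1) {
  ctr <- cellCenters(domain)
  ext <- max(domain@nCols, domain@nRows) * domain@cellSizeKm
  w <- widthFrac * ext
  s <- numeric(nCells(domain))
  for (b in seq_len(nBumps)) {
    cx <- runif(1, 0, domain@nCols * domain@cellSizeKm)
    cy <- runif(1, 0, domain@nRows * domain@cellSizeKm)
    s <- s + rnorm(1, 0, ampSd) *
      exp(-((ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2) / (2 * w^2))
  }
  s
}

#' Day axis implied by a synthetic configuration
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return Sorted \code{Date} vector of the modeled days.
#' @export
configDays <- function(cfg) {
  out <- lapply(cfg@months, function(m) {
    first <- as.Date(sprintf("%d-%02d-01", cfg@year, m))
    last <- seq(first, by = "month", length.out = 2)[2] - 1
    dd <- seq(first, last, by = "day")
    if (!is.na(cfg@daysPerMonth)) dd <- head(dd, cfg@daysPerMonth)
    dd
  })
  sort(do.call(c, out))
}

## contiguous rectangular tiling of the grid into nRegions blocks
regionTiling <- function(nRows, nCols, nRegions) {
  rr <- floor(sqrt(nRegions))
  while (nRegions %% rr != 0L) rr <- rr - 1L
  rc <- nRegions %/% rr
  idx <- seq_len(nRows * nCols) - 1L
  row <- idx %/% nCols; col <- idx %% nCols
  br <- pmin(row %/% ceiling(nRows / rr), rr - 1L)
  bc <- pmin(col %/% ceiling(nCols / rc), rc - 1L)
  as.integer(br * rc + bc + 1L)
}

#' Generate the synthetic domain, population and station network
#'
#' Population is drawn from a clustered log-normal surface; urbanization
#' classes are assigned by population-density tertiles (upper tertile urban,
#' middle suburban, lower rural); stations are placed in distinct cells with
#' probability proportional to population, emulating networks concentrated in
#' populated lowlands. Fully reproducible under the config seed.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return List with elements \code{domain} (\linkS4class{GridDomain}),
#'   \code{pop} (\linkS4class{PopulationGrid}) and \code{net}
#'   (\linkS4class{StationNetwork}, no hourly series yet).
#' @export
generateDomain <- function(cfg) {
  n <- cfg@nRows * cfg@nCols
  if (cfg@nStations > n) stop("nStations exceeds the number of cells")
  domain <- gridDomain(cfg@nRows, cfg@nCols, cfg@cellSizeKm,
                       regionId = regionTiling(cfg@nRows, cfg@nCols, cfg@nRegions),
                       regionNames = paste0("R", seq_len(cfg@nRegions)))

  set.seed(subSeed(cfg@seed, 1L))
  bumps <- pmax(smoothSurface(domain, cfg@popClusters, 0.12, 1), 0)
  if (max(bumps) > 0) bumps <- bumps / max(bumps)
  logPop <- 3.5 + 2.2 * bumps + rnorm(n, 0, cfg@popLogSd)
  population <- round(exp(logPop))
  g <- ceiling(3 * rank(population, ties.method = "first") / n)
  pop <- populationGrid(population, as.integer(g - 1L))

  set.seed(subSeed(cfg@seed, 2L))
  cells <- sample.int(n, cfg@nStations, replace = FALSE,
                      prob = population + 1e-9)
  ctr <- cellCenters(domain)[cells, , drop = FALSE]
  st <- data.frame(stationId = sprintf("ST%03d", seq_len(cfg@nStations)),
                   x_km = ctr[, 1], y_km = ctr[, 2], hostCell = as.integer(cells))
  list(domain = domain, pop = pop, net = stationNetwork(st, domain))
}

#' Generate the predictor blocks
#'
#' Emissions follow static population-correlated spatial surfaces modulated
#' by species-specific seasonal day factors; boundary-condition series are
#' seasonal sinusoids plus AR(1) synoptic noise; meteorology combines a
#' seasonal cycle, an elevation lapse, AR(1) synoptic signals and smooth
#' spatial texture; land use holds the urban fraction (population-derived),
#' forest fraction and a static elevation ridge.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @param domain the grid.
#' @param pop the \linkS4class{PopulationGrid} (drives emissions and urban
#'   fraction).
#' @return A \linkS4class{PredictorBlocks}.
#' @export
generatePredictors <- function(cfg, domain, pop) {
  set.seed(subSeed(cfg@seed, 3L))
  days <- configDays(cfg)
  n <- nCells(domain); nd <- length(days)
  doy <- as.integer(strftime(days, "%j"))

  relPop <- pop@population / max(pop@population)
  spBase <- c(pm25 = 5, nox = 20, sox = 8, nh3 = 6, vocs = 25)
  phase <- c(pm25 = 0, nox = 0.4, sox = 0.8, nh3 = 1.2, vocs = 1.6)
  em <- lapply(names(spBase), function(sp) {
    spat <- spBase[[sp]] * relPop^0.6 * exp(rnorm(n, 0, 0.3))
    # seasonal cycle plus day-to-day activity variability (AR1, lognormal)
    daily <- (1 + 0.25 * sin(2 * pi * doy / 365 + phase[[sp]])) *
      exp(ar1Series(nd, 0.5, 0.25))
    outer(spat, daily)
  })
  names(em) <- names(spBase)

  bc <- data.frame(
    bc_pm = pmax(8 + 5 * sin(2 * pi * (doy - 15) / 365) + ar1Series(nd, 0.7, 2), 0),
    bc_o3 = pmax(40 + 10 * sin(2 * pi * (doy + 60) / 365) + ar1Series(nd, 0.7, 3), 0))

  ctr <- cellCenters(domain)
  ridge <- 2.2 * exp(-((ctr[, 1] - 0.7 * cfg@nCols * cfg@cellSizeKm) /
                       (0.15 * cfg@nCols * cfg@cellSizeKm))^2)  # elevation, km
  seasT <- 12 + 9 * sin(2 * pi * (doy - 105) / 365)
  synT <- ar1Series(nd, 0.8, 1.2)
  synW <- ar1Series(nd, 0.6, 0.8)
  texT <- smoothSurface(domain, 6, 0.25, 0.8)
  texW <- smoothSurface(domain, 6, 0.25, 0.6)
  mt <- list(
    t850 = outer(-6.5 * ridge + texT, rep(1, nd)) + outer(rep(1, n), seasT + synT),
    w850 = pmax(outer(4 + texW, rep(1, nd)) +
                outer(rep(1, n), 1.5 * sin(2 * pi * doy / 365) + synW), 0.1),
    t690 = outer(-6.5 * ridge + 0.8 * texT, rep(1, nd)) +
           outer(rep(1, n), seasT - 8 + 0.9 * synT + ar1Series(nd, 0.5, 0.6)),
    w690 = pmax(outer(5 + 0.7 * texW, rep(1, nd)) +
                outer(rep(1, n), 1.3 * synW + ar1Series(nd, 0.5, 0.5)), 0.1))

  lu <- data.frame(lu_urban = relPop^0.5,
                   lu_forest = pmax(1 - relPop^0.5, 0) * (0.3 + 0.7 * ridge / max(ridge)),
                   lu_elev = ridge)
  new("PredictorBlocks", em = em, bc = bc, mt = mt, lu = lu,
      days = days, domain = domain)
}

zs <- function(m) (m - mean(m)) / stats::sd(m)

## component bias transforms: one block each, standardized driver plus a
## systematic offset so each component carries a nonzero mean bias
biasTransforms <- function(blocks, pollutant) {
  nd <- length(blocks@days); n <- nCells(blocks@domain)
  # log-emissions: the raw surfaces are lognormal-skewed, the log is well scaled
  emDriver <- if (pollutant == "pm25") log(blocks@em$pm25) else log(blocks@em$nox)
  bcDriver <- if (pollutant == "pm25") blocks@bc$bc_pm else blocks@bc$bc_o3
  doy <- as.integer(strftime(blocks@days, "%j"))
  list(
    em = 0.3 + 0.3 * zs(emDriver),
    bc = outer(rep(1, n), 0.5 + 0.3 * zs(bcDriver)),
    mt = 0.4 + 0.21 * zs(blocks@mt$t850) + 0.09 * zs(blocks@mt$w850),
    # the static land-use surface is modulated by a semiannual weight
    # (vegetation/surface-type bias varies over the year); without day
    # variation the LU delta series would be constant and inseparable from
    # the intercept
    lu = outer(0.5 + 0.3 * zs(blocks@lu$lu_elev),
               1 + 0.4 * cos(4 * pi * (doy - 45) / 365)))
}

#' Generate truth and biased CTM concentration fields
#'
#' The latent truth is a documented smooth log-linear function of the
#' predictor blocks (so concentrations are strictly positive); the CTM field
#' adds, for each component k in \{EM, BC, MT, LU\}, a known bias surface
#' \eqn{\gamma_k f_k} (each \eqn{f_k} a standardized-plus-offset transform of
#' one block only) plus white noise, and clips at zero. The component bias
#' surfaces are returned so downstream apportionment can be validated against
#' the injected ground truth.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @param blocks matching \linkS4class{PredictorBlocks}.
#' @param pollutant \code{"pm25"} or \code{"o3"}.
#' @param noise if \code{FALSE}, the white-noise term is suppressed.
#' @return List with \code{truth} and \code{ctm}
#'   (\linkS4class{ConcentrationField}s), \code{bias} (named list of the four
#'   injected cell x day bias surfaces) and \code{noise} (the white-noise
#'   matrix).
#' @export
generateFields <- function(cfg, blocks, pollutant = c("pm25", "o3"),
                           noise = TRUE) {
  pollutant <- match.arg(pollutant)
  domain <- blocks@domain
  n <- nCells(domain); nd <- length(blocks@days)

  if (pollutant == "pm25") {
    truthM <- 20 * exp(0.20 * zs(log(blocks@em$pm25)) +
                       outer(rep(1, n), 0.15 * zs(blocks@bc$bc_pm)) +
                       0.08 * zs(blocks@mt$t850) - 0.12 * zs(blocks@mt$w850) +
                       0.06 * zs(log(blocks@em$pm25)) * zs(blocks@mt$t850) -
                       outer(0.08 * zs(blocks@lu$lu_elev), rep(1, nd)))
  } else {
    truthM <- 55 * exp(outer(rep(1, n), 0.10 * zs(blocks@bc$bc_o3)) +
                       0.12 * zs(blocks@mt$t850) - 0.06 * zs(log(blocks@em$nox)) +
                       0.05 * zs(blocks@mt$w690) +
                       0.04 * zs(blocks@mt$t850) * zs(blocks@mt$w690) -
                       outer(0.04 * zs(blocks@lu$lu_urban), rep(1, nd)))
  }

  f <- biasTransforms(blocks, pollutant)
  g <- cfg@gamma * cfg@gammaPollutantScale[[pollutant]]
  bias <- lapply(c(em = "em", bc = "bc", mt = "mt", lu = "lu"),
                 function(k) g[[k]] * f[[k]])

  set.seed(subSeed(cfg@seed, if (pollutant == "pm25") 4L else 5L))
  eps <- if (noise) matrix(rnorm(n * nd, 0, cfg@ctmNoiseSd[[pollutant]]), n, nd)
         else matrix(0, n, nd)

  ctmM <- pmax(truthM + Reduce(`+`, bias) + eps, 0)
  list(truth = concentrationField(pollutant, truthM, blocks@days, domain),
       ctm = concentrationField(pollutant, ctmM, blocks@days, domain),
       bias = bias, noise = eps)
}

#' Diurnal profile used to expand daily values into hourly series
#'
#' For PM2.5 the 24 profile weights average exactly 1, so the daily mean of
#' the hourly series equals the daily value. For O3 the profile is a midday
#' photochemical peak normalized so that its maximum same-day 8-h running
#' mean equals 1, so the MDA8 of the hourly series equals the daily value.
#'
#' @param pollutant \code{"pm25"} or \code{"o3"}.
#' @return Numeric vector of 24 positive weights (hours 0-23).
#' @export
hourlyProfile <- function(pollutant = c("pm25", "o3")) {
  pollutant <- match.arg(pollutant)
  h <- 0:23
  if (pollutant == "pm25") return(1 + 0.3 * cos(2 * pi * (h - 9) / 24))
  q <- 0.15 + exp(-((h - 14) / 4)^2)
  win <- vapply(0:16, function(s) mean(q[(s + 1):(s + 8)]), numeric(1))
  q / max(win)
}

#' Sample station observations from the truth field
#'
#' Each station-day value is the truth at the station's host cell plus
#' Gaussian noise (floored at zero); the daily value is expanded into an
#' hourly series by the documented diurnal profile so the daily-metric
#' operators (daily mean, MDA8) are exercised end to end.
#'
#' @param truth a truth \linkS4class{ConcentrationField}.
#' @param net a \linkS4class{StationNetwork}.
#' @param noiseSd Gaussian sd of the observation error (>= 0).
#' @param seed RNG seed for the observation noise.
#' @return \code{net} with the hourly series for this pollutant appended.
#' @export
sampleObservations <- function(truth, net, noiseSd, seed) {
  stopifnot(noiseSd >= 0)
  set.seed(seed)
  st <- net@stations
  days <- truth@days
  prof <- hourlyProfile(truth@pollutant)
  rows <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    daily <- pmax(truth@values[st$hostCell[i], ] + rnorm(length(days), 0, noiseSd), 0)
    tt <- rep(as.POSIXct(paste(days, "00:00:00"), tz = "UTC"), each = 24L) +
      rep(0:23, times = length(days)) * 3600
    rows[[i]] <- data.frame(stationId = st$stationId[i], time = tt,
                            pollutant = truth@pollutant,
                            value = as.vector(outer(prof, daily)))
  }
  hourly <- do.call(rbind, rows)
  new("StationNetwork", stations = st, hourly = rbind(net@hourly, hourly),
      domain = net@domain)
}

#' A complete synthetic study
#'
#' @slot cfg the generating configuration.
#' @slot domain,pop,net the spatial setting and observation network (with
#'   hourly series for both pollutants).
#' @slot blocks the predictor blocks.
#' @slot fields per-pollutant list as returned by \code{\link{generateFields}}
#'   (truth, ctm, injected bias surfaces, noise).
#' @export
setClass("SyntheticStudy",
  representation(cfg = "SyntheticConfig", domain = "GridDomain",
                 pop = "PopulationGrid", net = "StationNetwork",
                 blocks = "PredictorBlocks", fields = "list"))

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy: %d x %d grid, %d stations, %d days, seed %d\n",
              object@domain@nRows, object@domain@nCols,
              nrow(object@net@stations), length(object@blocks@days),
              object@cfg@seed))
})

#' Run the full synthetic-study generator
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return A \linkS4class{SyntheticStudy} with both pollutants' fields and
#'   station series.
#' @examples
#' study <- simulateStudy(syntheticConfig(seed = 7, nRows = 6, nCols = 8,
#'                                        nStations = 5, daysPerMonth = 3L))
#' study
#' @export
simulateStudy <- function(cfg) {
  dm <- generateDomain(cfg)
  blocks <- generatePredictors(cfg, dm$domain, dm$pop)
  fields <- list(pm25 = generateFields(cfg, blocks, "pm25"),
                 o3 = generateFields(cfg, blocks, "o3"))
  net <- dm$net
  net <- sampleObservations(fields$pm25$truth, net, cfg@obsNoiseSd[["pm25"]],
                            subSeed(cfg@seed, 6L))
  net <- sampleObservations(fields$o3$truth, net, cfg@obsNoiseSd[["o3"]],
                            subSeed(cfg@seed, 7L))
  new("SyntheticStudy", cfg = cfg, domain = dm$domain, pop = dm$pop,
      net = net, blocks = blocks, fields = fields)
}

#' Ground-truth scenario fields for a synthetic study
#'
#' Builds the ideal scenario bundle implied by the injected biases: S1 is the
#' latent truth (all components corrected), and each single-block scenario Sk
#' is the CTM field with exactly its component's bias surface removed. This
#' is the oracle against which the bias-apportionment stage is validated
#' independently of any learner.
#'
#' @param study a \linkS4class{SyntheticStudy}.
#' @param pollutant \code{"pm25"} or \code{"o3"}.
#' @return A \linkS4class{ScenarioConcentrations}.
#' @export
oracleScenarios <- function(study, pollutant = c("pm25", "o3")) {
  pollutant <- match.arg(pollutant)
  fl <- study@fields[[pollutant]]
  days <- fl$ctm@days; dom <- fl$ctm@domain
  mk <- function(v) concentrationField(pollutant, pmax(v, 0), days, dom)
  scenarioConcentrations(fl$ctm, list(
    S1 = fl$truth,
    S2 = mk(fl$ctm@values - fl$bias$em),
    S3 = mk(fl$ctm@values - fl$bias$bc),
    S4 = mk(fl$ctm@values - fl$bias$mt),
    S5 = mk(fl$ctm@values - fl$bias$lu)))
}
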
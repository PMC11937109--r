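#' @include AllClasses.R domain.R synthetic.R
NULL

## Plain-text interchange formats: gridded layers and fields as long-format
## CSV keyed by cell (row-major) and date, station series as the standard
## long CSV (station_id, x_km, y_km, timestamp, pollutant, value), run
## configuration as YAML, run metadata as JSON.

#' Write / read a concentration field as CSV
#'
#' Long format with columns \code{cell}, \code{row}, \code{col}, \code{date},
#' \code{value} (empty value = missing).
#'
#' @param field a \linkS4class{ConcentrationField}.
#' @param path output CSV path.
#' @return \code{writeFieldCsv} returns \code{path} invisibly;
#'   \code{readFieldCsv} returns the \linkS4class{ConcentrationField}.
#' @export
writeFieldCsv <- function(field, path) {
  dom <- field@domain
  n <- nCells(dom); nd <- length(field@days)
  idx <- seq_len(n) - 1L
  df <- data.frame(cell = rep(seq_len(n), nd),
                   row = rep(idx %/% dom@nCols + 1L, nd),
                   col = rep(idx %% dom@nCols + 1L, nd),
                   date = rep(as.character(field@days), each = n),
                   value = as.vector(field@values))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFieldCsv
#' @param pollutant pollutant of the stored field.
#' @param domain the \linkS4class{GridDomain} the file refers to.
#' @export
readFieldCsv <- function(path, pollutant, domain) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  days <- sort(unique(as.Date(df$date)))
  m <- matrix(NA_real_, nCells(domain), length(days))
  m[cbind(df$cell, match(as.Date(df$date), days))] <- df$value
  concentrationField(pollutant, m, days, domain)
}

#' Write / read the domain layers (regions, population, urban class)
#'
#' One row per cell: \code{cell}, \code{row}, \code{col}, \code{region},
#' \code{population}, \code{urban_class} (0 rural / 1 suburban / 2 urban).
#'
#' @param domain a \linkS4class{GridDomain}.
#' @param pop a \linkS4class{PopulationGrid}.
#' @param path CSV path.
#' @return \code{writeDomainCsv} returns \code{path} invisibly;
#'   \code{readDomainCsv} returns \code{list(domain, pop)}.
#' @export
writeDomainCsv <- function(domain, pop, path) {
  idx <- seq_len(nCells(domain)) - 1L
  df <- data.frame(cell = idx + 1L, row = idx %/% domain@nCols + 1L,
                   col = idx %% domain@nCols + 1L,
                   region = regionIds(domain),
                   population = pop@population,
                   urban_class = pop@urbanClass)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeDomainCsv
#' @param cellSizeKm cell size of the stored grid.
#' @export
readDomainCsv <- function(path, cellSizeKm = 3) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(df$cell), , drop = FALSE]
  regions <- unique(df$region[order(df$cell)])
  domain <- gridDomain(max(df$row), max(df$col), cellSizeKm,
                       regionId = match(df$region, regions),
                       regionNames = regions)
  list(domain = domain,
       pop = populationGrid(df$population, as.integer(df$urban_class)))
}

#' Write / read station hourly series as CSV
#'
#' Long format: \code{station_id}, \code{x_km}, \code{y_km},
#' \code{timestamp} (ISO-8601, UTC), \code{pollutant}, \code{value}.
#'
#' @param net a \linkS4class{StationNetwork}.
#' @param path CSV path.
#' @return \code{writeStationsCsv} returns \code{path} invisibly;
#'   \code{readStationsCsv} returns the \linkS4class{StationNetwork}.
#' @export
writeStationsCsv <- function(net, path) {
  st <- net@stations
  h <- net@hourly
  i <- match(h$stationId, st$stationId)
  df <- data.frame(station_id = h$stationId, x_km = st$x_km[i],
                   y_km = st$y_km[i],
                   timestamp = format(h$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   pollutant = h$pollutant, value = h$value)
  if (nrow(h) == 0L)
    df <- data.frame(station_id = st$stationId, x_km = st$x_km,
                     y_km = st$y_km, timestamp = "", pollutant = "",
                     value = NA_real_)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeStationsCsv
#' @param domain the \linkS4class{GridDomain} used for collocation.
#' @export
readStationsCsv <- function(path, domain) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  st <- unique(df[, c("station_id", "x_km", "y_km")])
  names(st)[1] <- "stationId"
  keep <- !is.na(df$value) & nzchar(df$timestamp)
  hourly <- data.frame(
    stationId = df$station_id[keep],
    time = as.POSIXct(df$timestamp[keep], format = "%Y-%m-%dT%H:%M:%SZ",
                      tz = "UTC"),
    pollutant = df$pollutant[keep], value = df$value[keep])
  stationNetwork(st, domain, hourly)
}

#' Write a synthetic study to a directory
#'
#' Emits the full study in the package's CSV formats plus a JSON sidecar
#' (\code{truth.json}) recording the generating seed, the injected component
#' gains and the file inventory, including the per-component ground-truth
#' bias surfaces (as fields of the CTM day axis).
#'
#' @param study a \linkS4class{SyntheticStudy}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeDomainCsv(study@domain, study@pop, file.path(dir, "domain.csv"))
  writeStationsCsv(study@net, file.path(dir, "stations.csv"))
  days <- study@blocks@days
  for (p in names(study@fields)) {
    fl <- study@fields[[p]]
    writeFieldCsv(fl$ctm, file.path(dir, paste0("ctm_", p, ".csv")))
    writeFieldCsv(fl$truth, file.path(dir, paste0("truth_", p, ".csv")))
    for (k in names(fl$bias)) {
      # bias surfaces are signed, so they are written as raw matrices rather
      # than through the non-negative field contract
      df <- data.frame(cell = rep(seq_len(nrow(fl$bias[[k]])), length(days)),
                       date = rep(as.character(days), each = nrow(fl$bias[[k]])),
                       value = as.vector(fl$bias[[k]]))
      write.csv(df, file.path(dir, sprintf("bias_%s_%s.csv", p, k)),
                row.names = FALSE, quote = FALSE)
    }
  }
  for (sp in names(study@blocks@em)) {
    df <- data.frame(cell = rep(seq_len(nCells(study@domain)), length(days)),
                     date = rep(as.character(days),
                                each = nCells(study@domain)),
                     value = as.vector(study@blocks@em[[sp]]))
    write.csv(df, file.path(dir, sprintf("em_%s.csv", sp)),
              row.names = FALSE, quote = FALSE)
  }
  for (v in names(study@blocks@mt)) {
    df <- data.frame(cell = rep(seq_len(nCells(study@domain)), length(days)),
                     date = rep(as.character(days),
                                each = nCells(study@domain)),
                     value = as.vector(study@blocks@mt[[v]]))
    write.csv(df, file.path(dir, sprintf("mt_%s.csv", v)),
              row.names = FALSE, quote = FALSE)
  }
  write.csv(cbind(date = as.character(days), study@blocks@bc),
            file.path(dir, "bc.csv"), row.names = FALSE, quote = FALSE)
  write.csv(cbind(cell = seq_len(nCells(study@domain)), study@blocks@lu),
            file.path(dir, "lu.csv"), row.names = FALSE, quote = FALSE)
  sidecar <- list(seed = study@cfg@seed,
                  gamma = as.list(study@cfg@gamma),
                  gammaPollutantScale = as.list(study@cfg@gammaPollutantScale),
                  files = list.files(dir))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run configuration
#'
#' Bundles everything a pipeline run needs; mirrors the YAML schema read by
#' \code{\link{readRunConfigYaml}}.
#'
#' @param synthetic named list of \code{\link{syntheticConfig}} arguments
#'   (the run simulates its inputs).
#' @param pollutants pollutants to process.
#' @param scenarios scenarios to fit; apportionment needs all of S1-S5.
#' @param learners candidate learners; with several, the best non-overfit S1
#'   test R-squared picks the one used for all scenarios.
#' @param seed master seed recorded in the manifest.
#' @param cvFolds cross-validation folds.
#' @param crf optional named list per pollutant with entries \code{e0},
#'   \code{beta} (named rural/suburban/urban or single), \code{c0};
#'   defaults from \code{\link{defaultCRFParams}}.
#' @param outDir output directory.
#' @return A validated list of class \code{"runConfig"}.
#' @export
runConfig <- function(synthetic = list(), pollutants = c("pm25", "o3"),
                      scenarios = c("S1", "S2", "S3", "S4", "S5"),
                      learners = "boosted_trees", seed = 1L, cvFolds = 10L,
                      crf = NULL, outDir = "mlmmf-out") {
  stopifnot(all(pollutants %in% c("pm25", "o3")),
            all(scenarios %in% c("S1", "S2", "S3", "S4", "S5")),
            "S1" %in% scenarios,
            all(learners %in% c("knn", "tree", "forest", "boosted_trees")))
  structure(list(synthetic = synthetic, pollutants = pollutants,
                 scenarios = scenarios, learners = learners,
                 seed = as.integer(seed), cvFolds = as.integer(cvFolds),
                 crf = crf, outDir = outDir), class = "runConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   \code{\link{runConfig}}.
#' @return A \code{"runConfig"}.
#' @export
readRunConfigYaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(runConfig)))]
  if (!is.null(args$crf))
    args$crf <- lapply(args$crf, function(p) {
      p$beta <- unlist(p$beta); p
    })
  do.call(runConfig, args)
}

crfFromConfig <- function(cfg, pollutant) {
  spec <- cfg$crf[[pollutant]]
  if (is.null(spec)) return(defaultCRFParams(pollutant))
  crfParams(pollutant, e0 = spec$e0, beta = spec$beta,
            c0 = if (is.null(spec$c0)) c(pm25 = 25, o3 = 60)[[pollutant]]
                 else spec$c0)
}
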
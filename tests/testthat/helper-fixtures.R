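# Small in-code fixtures shared across test files.

tinyDomain <- function(nRows = 2, nCols = 2, cellSizeKm = 3, nRegions = 1) {
  regionId <- if (nRegions == 1) rep(1L, nRows * nCols)
              else as.integer(cut(seq_len(nRows * nCols), nRegions, labels = FALSE))
  gridDomain(nRows, nCols, cellSizeKm, regionId,
             paste0("R", seq_len(nRegions)))
}

tinyField <- function(values, domain, pollutant = "pm25",
                      days = as.Date("2016-01-01") + seq_len(NCOL(values)) - 1) {
  if (!is.matrix(values))
    values <- matrix(values, nCells(domain), length(days))
  concentrationField(pollutant, values, days, domain)
}

# network with stations at the centers of the given cells
tinyNet <- function(cells, domain, ids = sprintf("ST%02d", seq_along(cells))) {
  ctr <- cellCenters(domain)[cells, , drop = FALSE]
  stationNetwork(data.frame(stationId = ids, x_km = ctr[, 1], y_km = ctr[, 2]),
                 domain)
}

# hourly rows for one station-day
hourlyDay <- function(stationId, day, values24, pollutant = "pm25") {
  keep <- !is.na(values24)
  data.frame(
    stationId = stationId,
    time = as.POSIXct(paste(day, "00:00:00"), tz = "UTC") +
      (which(keep) - 1L) * 3600,
    pollutant = pollutant, value = values24[keep])
}

smallStudy <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, nRows = 10L, nCols = 12L, nStations = 8L,
         daysPerMonth = 5L),
    list(...))
  simulateStudy(do.call(syntheticConfig, args))
}

# brute-force MDA8: enumerate all 24 start hours explicitly
oracleMda8 <- function(h24, nxt7 = rep(NA_real_, 7)) {
  ext <- c(h24, nxt7)
  wm <- rep(NA_real_, 24)
  for (s in 1:24) {
    w <- ext[s:(s + 7)]
    if (sum(!is.na(w)) >= 6) wm[s] <- mean(w, na.rm = TRUE)
  }
  if (sum(!is.na(wm)) < 18) return(NA_real_)
  max(wm, na.rm = TRUE)
}

# injected contribution shares implied by a study's ground-truth surfaces
injectedShares <- function(study, pollutant) {
  P <- study@pop@population
  contrib <- vapply(study@fields[[pollutant]]$bias,
                    function(b) mean(colSums(P * b) / sum(P)), numeric(1))
  abs(contrib) / sum(abs(contrib))
}
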
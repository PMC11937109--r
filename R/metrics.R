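#' @include AllClasses.R domain.R synthetic.R
NULL

## Exposure metrics: the regulatory daily summaries used as the dependent
## variables of the fusion step, plus assembly of the learner-ready predictor
## table and its train/test split.

#' Daily PM2.5 metric from an hourly series
#'
#' 24-h arithmetic mean of the valid hours; the day is reported missing if
#' fewer than \code{minHours} of its 24 hours are valid (default 18, a common
#' regulatory completeness rule).
#'
#' @param hours numeric vector of 24 hourly values (hours 0-23), \code{NA}
#'   marking missing hours.
#' @param minHours minimum valid hours for a valid day.
#' @return The daily mean, or \code{NA} if the day is incomplete.
#' @export
dailyPm25 <- function(hours, minHours = 18L) {
  if (length(hours) != 24L) stop("hourly series must have 24 entries per day")
  ok <- !is.na(hours)
  if (sum(ok) < minHours) return(NA_real_)
  mean(hours[ok])
}

#' MDA8 ozone metric from an hourly series
#'
#' Maximum daily 8-h average: for each start hour 0-23 the mean of the 8-h
#' window beginning there (windows starting after hour 16 extend into the
#' next calendar day and the value is assigned to the start day). A window is
#' valid with at least \code{minWindowHours} of its 8 hours present (the mean
#' is over present hours); the day is valid with at least \code{minWindows}
#' of its 24 windows valid.
#'
#' @param hours numeric vector of 24 hourly values for the day.
#' @param nextHours the first 7 hourly values of the following day (\code{NA}
#'   when unavailable).
#' @param minWindowHours,minWindows completeness rules.
#' @return The MDA8 value, or \code{NA} if the day is incomplete.
#' @export
mda8O3 <- function(hours, nextHours = rep(NA_real_, 7L),
                   minWindowHours = 6L, minWindows = 18L) {
  if (length(hours) != 24L) stop("hourly series must have 24 entries per day")
  ext <- c(hours, nextHours[seq_len(7L)])
  means <- rep(NA_real_, 24L)
  for (s in 1:24) {
    w <- ext[s:(s + 7L)]
    if (sum(!is.na(w)) >= minWindowHours) means[s] <- mean(w, na.rm = TRUE)
  }
  if (sum(!is.na(means)) < minWindows) return(NA_real_)
  max(means, na.rm = TRUE)
}

#' Daily metrics for every station
#'
#' Applies \code{\link{dailyPm25}} or \code{\link{mda8O3}} to each station's
#' hourly series.
#'
#' @param net a \linkS4class{StationNetwork} with hourly data.
#' @param pollutant \code{"pm25"} or \code{"o3"}.
#' @return data.frame with columns \code{stationId}, \code{day},
#'   \code{value} (may be \code{NA}), one row per station-day present in the
#'   hourly record.
#' @export
stationDailyMetrics <- function(net, pollutant = c("pm25", "o3")) {
  pollutant <- match.arg(pollutant)
  h <- net@hourly[net@hourly$pollutant == pollutant, , drop = FALSE]
  if (nrow(h) == 0L) stop("no hourly data for pollutant ", pollutant)
  if (any(as.integer(format(h$time, "%M")) != 0L | h$time != trunc(h$time, "hours")))
    stop("hourly series must be aligned on the hour")
  h$day <- as.Date(h$time, tz = "UTC")
  h$hour <- as.integer(format(h$time, "%H", tz = "UTC"))
  out <- lapply(split(h, h$stationId), function(d) {
    days <- sort(unique(d$day))
    m <- matrix(NA_real_, 24L, length(days),
                dimnames = list(NULL, as.character(days)))
    m[cbind(d$hour + 1L, match(d$day, days))] <- d$value
    val <- vapply(seq_along(days), function(j) {
      if (pollutant == "pm25") return(dailyPm25(m[, j]))
      nxt <- if (j < length(days) && days[j + 1L] == days[j] + 1L)
        m[1:7, j + 1L] else rep(NA_real_, 7L)
      mda8O3(m[, j], nxt)
    }, numeric(1))
    data.frame(stationId = d$stationId[1], day = days, value = val)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## feature columns per block, in learner-table order
blockFeatureNames <- function(blocks) {
  list(em = paste0("em_", names(blocks@em)),
       bc = names(blocks@bc),
       mt = paste0("mt_", names(blocks@mt)),
       lu = names(blocks@lu))
}

## features for arbitrary (cell, dayIdx) record pairs
featureRows <- function(blocks, cells, dayIdx) {
  ij <- cbind(cells, dayIdx)
  em <- vapply(blocks@em, function(m) m[ij], numeric(length(cells)))
  mt <- vapply(blocks@mt, function(m) m[ij], numeric(length(cells)))
  if (length(cells) == 1L) { em <- t(em); mt <- t(mt) }
  colnames(em) <- paste0("em_", names(blocks@em))
  colnames(mt) <- paste0("mt_", names(blocks@mt))
  bc <- as.matrix(blocks@bc)[dayIdx, , drop = FALSE]
  lu <- as.matrix(blocks@lu)[cells, , drop = FALSE]
  cbind(em, bc, mt, lu)
}

#' Assemble the learner-ready predictor table
#'
#' One record per station-hosting cell and day with a valid observed daily
#' metric (the target). Predictors are the raw CTM value plus every feature
#' of the four blocks: emissions per species, boundary-condition series
#' (broadcast across cells), meteorology, and static land use (broadcast
#' across days). The feature-to-block mapping is attached as the
#' \code{"blocks"} attribute; scenario construction relies on it.
#'
#' @param ctm the raw CTM \linkS4class{ConcentrationField}.
#' @param blocks \linkS4class{PredictorBlocks} on the same domain.
#' @param net a \linkS4class{StationNetwork} with hourly data.
#' @param pollutant \code{"pm25"} or \code{"o3"}.
#' @return data.frame with key columns \code{stationId}, \code{cell},
#'   \code{day}, \code{region}, the \code{target}, \code{cmaq} and the block
#'   features; attribute \code{"blocks"} names the feature columns of each
#'   block.
#' @export
assembleTable <- function(ctm, blocks, net, pollutant = c("pm25", "o3")) {
  pollutant <- match.arg(pollutant)
  if (!identical(ctm@domain@regionId, blocks@domain@regionId) ||
      nCells(ctm@domain) != nCells(blocks@domain))
    stop("ctm and blocks must share the grid domain")
  met <- stationDailyMetrics(net, pollutant)
  met <- met[!is.na(met$value), , drop = FALSE]
  met <- met[met$day %in% blocks@days, , drop = FALSE]
  st <- net@stations
  cell <- st$hostCell[match(met$stationId, st$stationId)]
  dayIdx <- match(met$day, blocks@days)
  tab <- data.frame(stationId = met$stationId, cell = cell, day = met$day,
                    region = regionIds(ctm@domain)[cell],
                    target = met$value,
                    cmaq = ctm@values[cbind(cell, match(met$day, ctm@days))])
  tab <- cbind(tab, as.data.frame(featureRows(blocks, cell, dayIdx)))
  rownames(tab) <- NULL
  attr(tab, "blocks") <- blockFeatureNames(blocks)
  attr(tab, "pollutant") <- pollutant
  tab
}

#' Random train/test split of a predictor table
#'
#' Uniform random 60/40 split without replacement, reproducible under the
#' seed. \code{by = "station"} instead keeps whole stations together, for
#' leakage-sensitivity checks.
#'
#' @param table a predictor table from \code{\link{assembleTable}}.
#' @param seed RNG seed.
#' @param trainFrac training fraction (default 0.6).
#' @param by \code{"record"} (default) or \code{"station"}.
#' @return List with integer row indices \code{train} and \code{test} and the
#'   \code{seed}.
#' @export
splitTable <- function(table, seed, trainFrac = 0.6,
                       by = c("record", "station")) {
  by <- match.arg(by)
  n <- nrow(table)
  if (n < 5L) stop("too few records to split")
  set.seed(seed)
  if (by == "record") {
    train <- sort(sample.int(n, round(trainFrac * n)))
  } else {
    ids <- unique(table$stationId)
    tr <- sample(ids, max(1L, round(trainFrac * length(ids))))
    train <- which(table$stationId %in% tr)
  }
  list(train = train, test = setdiff(seq_len(n), train), seed = seed)
}
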
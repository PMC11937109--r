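test_that("roundHalfUp rounds halves away from zero", {
  expect_identical(roundHalfUp(0.5), 1)
  expect_identical(roundHalfUp(-0.5), -1)
  expect_identical(roundHalfUp(2.5), 3)
  expect_identical(roundHalfUp(68.5047), 69)
  expect_identical(roundHalfUp(1.25, 1), 1.3)
  expect_identical(roundHalfUp(c(1.4, 1.6, -1.5)), c(1, 2, -2))
})

test_that("crfDeaths matches the closed form and its limits", {
  dom <- tinyDomain(1, 1)
  p <- populationGrid(1000, 2L)
  f35 <- tinyField(matrix(35), dom)
  par <- crfParams("pm25", e0 = 365, beta = 0.001)

  # E0 * P * (1 - exp(-beta * 10)) * (1/365), with E0 = 365
  expect_equal(crfDeaths(f35, p, par), 1000 * (1 - exp(-0.01)))

  # below-threshold exposure produces exactly zero
  expect_equal(crfDeaths(tinyField(matrix(25), dom), p, par), 0)
  expect_equal(crfDeaths(tinyField(matrix(10), dom), p, par), 0)

  # linear limit: for tiny beta*(C - C0), y ~ E0*P*beta*(C-C0)*A
  parT <- crfParams("pm25", e0 = 0.007, beta = 1e-5)
  y <- crfDeaths(f35, p, parT)
  expect_equal(y, 0.007 * 1000 * 1e-5 * 10 / 365, tolerance = 1e-3)

  # monotonicity and the saturation bound E0*P*A per cell-day
  ys <- vapply(c(30, 40, 60, 200), function(cc)
    crfDeaths(tinyField(matrix(cc), dom), p, par), numeric(1))
  expect_true(all(diff(ys) > 0))
  expect_true(all(ys < 365 * 1000 / 365))

  # missing cell-days contribute nothing
  fNA <- tinyField(matrix(c(35, NA), 1, 2), dom,
                   days = as.Date("2016-01-01") + 0:1)
  expect_equal(crfDeaths(fNA, p, par), crfDeaths(f35, p, par))

  # pollutant mismatch between exposure units and threshold is an error
  expect_error(crfDeaths(tinyField(matrix(80), dom, pollutant = "o3"), p, par),
               "units")
})

test_that("heterogeneous risk uses each cell's urbanization class", {
  dom <- tinyDomain(1, 3)
  pop <- populationGrid(c(100, 200, 300), c(0L, 1L, 2L))
  f <- tinyField(matrix(35, 3, 1), dom)
  beta <- c(rural = 0.001, suburban = 0.002, urban = 0.004)
  par <- crfParams("pm25", e0 = 365, beta = beta)
  want <- 100 * (1 - exp(-0.01)) + 200 * (1 - exp(-0.02)) +
          300 * (1 - exp(-0.04))
  expect_equal(crfDeaths(f, pop, par), want)

  # averaged scheme: population-weighted beta
  avg <- averageRisk(par, pop)
  expect_length(avg@beta, 1)
  expect_equal(unname(avg@beta),
               (100 * 0.001 + 200 * 0.002 + 300 * 0.004) / 600)
  # averaging an already-averaged parameter set is the identity
  expect_identical(averageRisk(avg, pop)@beta, avg@beta)
})

test_that("observation-derived exposure is a nearest-station lookup", {
  dom <- tinyDomain(1, 3)
  net <- tinyNet(c(1L, 3L), dom, ids = c("A", "B"))
  days <- as.Date("2016-01-01") + 0:1
  met <- data.frame(stationId = rep(c("A", "B"), each = 2),
                    day = rep(days, 2), value = c(10, 12, 30, NA))
  f <- exposureFromObservations(met, net, "pm25")
  # cell 1 -> A, cell 3 -> B, cell 2 equidistant -> A by id order
  expect_equal(f@values[, 1], c(10, 10, 30))
  expect_equal(f@values[1:2, 2], c(12, 12))
  expect_true(is.na(f@values[3, 2]))  # missing station-day propagates

  # exhaustive check on a random 5x5 network
  set.seed(51)
  dom2 <- tinyDomain(5, 5)
  net2 <- tinyNet(sample(25, 4), dom2, ids = c("N1", "N2", "N3", "N4"))
  met2 <- data.frame(stationId = c("N1", "N2", "N3", "N4"),
                     day = as.Date("2016-01-01"), value = c(5, 10, 20, 40))
  f2 <- exposureFromObservations(met2, net2, "pm25")
  near <- nearestStation(1:25, net2)
  expect_equal(f2@values[, 1], met2$value[match(near, met2$stationId)])
})

test_that("improvement ratio and bias percent match their definitions", {
  expect_identical(improvementRatio(7374, 7454, 13331), 99)
  expect_identical(improvementRatio(7454, 7454, 13331), 100)
  expect_identical(improvementRatio(13331, 7454, 13331), 0)
  # scenarios can be worse than the raw model (negative ratio)
  expect_lt(improvementRatio(20000, 7454, 13331), 0)
  expect_error(improvementRatio(5, 10, 10), "coincide")
  expect_equal(improvementRatio(3082, 3641, 3000, rounded = FALSE),
               (1 - abs(3082 - 3641) / abs(3000 - 3641)) * 100)

  expect_identical(biasPercent(10218, 7454), 37)
  expect_identical(biasPercent(7454, 7454), 0)
  expect_error(biasPercent(5, 0), "positive")
})

test_that("scenarioDeathsTable covers regions, sources and ratios", {
  st <- smallStudy(seed = 53, nRegions = 2L)
  sc <- oracleScenarios(st, "pm25")
  met <- stationDailyMetrics(st@net, "pm25")
  obs <- exposureFromObservations(met, st@net, "pm25")
  par <- defaultCRFParams("pm25")
  tab <- scenarioDeathsTable(sc, obs, st@pop, par)

  expect_setequal(unique(tab$region), c("R1", "R2", "Total"))
  expect_setequal(unique(tab$source),
                  c("observation", "cmaq", "S1", "S2", "S3", "S4", "S5"))
  expect_identical(nrow(tab), 3L * 7L)
  # per-source regional deaths sum to the domain total
  for (s in unique(tab$source)) {
    d <- tab[tab$source == s, ]
    expect_equal(d$deaths[d$region == "Total"],
                 sum(d$deaths[d$region != "Total"]), tolerance = 1e-9)
  }
  # improvement ratios only for the single-block scenarios
  expect_true(all(is.na(tab$ir[tab$source %in% c("observation", "cmaq", "S1")])))
  tot <- tab[tab$region == "Total", ]
  y <- setNames(tot$deaths, tot$source)
  expect_equal(tot$ir[tot$source == "S3"],
               improvementRatio(y[["S3"]], y[["S1"]], y[["cmaq"]]))
})

test_that("sensitivityMatrix is complete and referenced to fused/heterogeneous", {
  st <- smallStudy(seed = 55, nRegions = 2L)
  sc <- oracleScenarios(st, "pm25")
  met <- stationDailyMetrics(st@net, "pm25")
  obs <- exposureFromObservations(met, st@net, "pm25")
  het <- defaultCRFParams("pm25")
  avg <- averageRisk(het, st@pop)
  sources <- list(observation = obs, cmaq = sc@cmaq, mmf = sc@fused$S1)
  m <- sensitivityMatrix(sources, st@pop, avg, het)

  expect_identical(nrow(m), 3L * 3L * 2L)  # (2 regions + Total) x 3 x 2
  ref <- m[m$source == "mmf" & m$scheme == "heterogeneous", ]
  expect_true(all(is.na(ref$biasPct)))
  other <- m[!(m$source == "mmf" & m$scheme == "heterogeneous") &
               m$region == "Total", ]
  refY <- ref$deaths[ref$region == "Total"]
  expect_equal(other$biasPct,
               roundHalfUp((other$deaths - refY) / refY * 100))

  # identical schemes collapse the scheme axis
  m2 <- sensitivityMatrix(sources, st@pop, het, het)
  d1 <- m2$deaths[m2$scheme == "average"]
  d2 <- m2$deaths[m2$scheme == "heterogeneous"]
  expect_equal(d1, d2)

  expect_error(sensitivityMatrix(list(cmaq = sc@cmaq), st@pop, avg, het),
               "mmf")
})
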
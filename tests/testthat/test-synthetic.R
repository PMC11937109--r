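test_that("generator is deterministic under the seed and streams are isolated", {
  a <- smallStudy(seed = 11)
  b <- smallStudy(seed = 11)
  expect_identical(a@fields$pm25$ctm@values, b@fields$pm25$ctm@values)
  expect_identical(a@fields$o3$truth@values, b@fields$o3$truth@values)
  expect_identical(a@net@hourly, b@net@hourly)
  expect_identical(a@pop@population, b@pop@population)

  c <- smallStudy(seed = 12)
  expect_false(identical(a@fields$pm25$ctm@values, c@fields$pm25$ctm@values))

  # adding stations must not perturb fields or population (per-artifact streams)
  d <- smallStudy(seed = 11, nStations = 10L)
  expect_identical(a@fields$pm25$ctm@values, d@fields$pm25$ctm@values)
  expect_identical(a@pop@population, d@pop@population)
})

test_that("domain generation: tertile classes and population-seeking stations", {
  cfg <- syntheticConfig(seed = 5, nRows = 3L, nCols = 3L, nStations = 2L,
                         nRegions = 1L)
  dm <- generateDomain(cfg)
  expect_identical(as.vector(table(dm$pop@urbanClass)), rep(3L, 3))
  expect_identical(sort(unique(dm$pop@urbanClass)), 0:2)
  expect_true(all(dm$pop@population >= 0))

  # stations should sit in more-populated cells than average (over seeds)
  hits <- vapply(1:20, function(s) {
    dm <- generateDomain(syntheticConfig(seed = s, nRows = 8L, nCols = 8L,
                                         nStations = 6L, nRegions = 1L))
    mean(dm$pop@population[dm$net@stations$hostCell]) >
      mean(dm$pop@population)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("injected bias obeys the configured gains exactly", {
  # no gains, no noise: CTM equals truth bit-for-bit
  cfg0 <- syntheticConfig(seed = 3, nRows = 6L, nCols = 8L, nStations = 4L,
                          nRegions = 2L, daysPerMonth = 4L,
                          gamma = c(em = 0, bc = 0, mt = 0, lu = 0))
  dm <- generateDomain(cfg0)
  bl <- generatePredictors(cfg0, dm$domain, dm$pop)
  fl <- generateFields(cfg0, bl, "pm25", noise = FALSE)
  expect_equal(fl$ctm@values, fl$truth@values)
  expect_true(all(vapply(fl$bias, function(b) all(b == 0), logical(1))))

  # bc-only gain, no noise: mean bias is gamma_bc * mean(f_bc) = 5 * 0.5
  cfgB <- syntheticConfig(seed = 3, nRows = 6L, nCols = 8L, nStations = 4L,
                          nRegions = 2L, daysPerMonth = 4L,
                          gamma = c(em = 0, bc = 5, mt = 0, lu = 0))
  flB <- generateFields(cfgB, bl, "pm25", noise = FALSE)
  expect_equal(mean(flB$ctm@values - flB$truth@values), 2.5, tolerance = 1e-9)
  # and the o3 gain is scaled by the per-pollutant factor (1.8)
  flO <- generateFields(cfgB, bl, "o3", noise = FALSE)
  expect_equal(mean(flO$ctm@values - flO$truth@values), 2.5 * 1.8,
               tolerance = 1e-9)

  # huge negative gain: clipping keeps concentrations physical
  cfgN <- syntheticConfig(seed = 3, nRows = 6L, nCols = 8L, nStations = 4L,
                          nRegions = 2L, daysPerMonth = 4L,
                          gamma = c(em = 0, bc = -1e4, mt = 0, lu = 0))
  flN <- generateFields(cfgN, bl, "pm25", noise = FALSE)
  expect_true(all(flN$ctm@values >= 0))
  expect_true(any(flN$ctm@values == 0))
})

test_that("truth fields are strictly positive and CTM is non-negative", {
  st <- smallStudy(seed = 21)
  for (p in c("pm25", "o3")) {
    expect_true(all(st@fields[[p]]$truth@values > 0))
    expect_true(all(st@fields[[p]]$ctm@values >= 0))
  }
})

test_that("hourly profiles invert exactly through the daily metrics", {
  # pm25 weights average exactly 1; o3 max same-day 8-h mean is exactly 1
  expect_equal(mean(hourlyProfile("pm25")), 1, tolerance = 1e-12)
  q <- hourlyProfile("o3")
  win <- vapply(0:16, function(s) mean(q[(s + 1):(s + 8)]), numeric(1))
  expect_equal(max(win), 1, tolerance = 1e-12)

  # noiseless observations reproduce host-cell truth through the metric chain
  st <- smallStudy(seed = 13, obsNoiseSd = c(pm25 = 0, o3 = 0))
  for (p in c("pm25", "o3")) {
    met <- stationDailyMetrics(st@net, p)
    truth <- st@fields[[p]]$truth
    cell <- st@net@stations$hostCell[match(met$stationId,
                                           st@net@stations$stationId)]
    want <- truth@values[cbind(cell, match(met$day, truth@days))]
    expect_equal(met$value, want, tolerance = 1e-9)
  }
})

test_that("observation noise is unbiased at the configured scale", {
  st <- smallStudy(seed = 17, nStations = 12L, daysPerMonth = 8L)
  met <- stationDailyMetrics(st@net, "pm25")
  truth <- st@fields$pm25$truth
  cell <- st@net@stations$hostCell[match(met$stationId,
                                         st@net@stations$stationId)]
  err <- met$value - truth@values[cbind(cell, match(met$day, truth@days))]
  n <- length(err)
  expect_gt(n, 300)
  se <- st@cfg@obsNoiseSd[["pm25"]] / sqrt(n)
  expect_lt(abs(mean(err)), 3 * se)
  expect_lt(abs(sd(err) / st@cfg@obsNoiseSd[["pm25"]] - 1), 0.15)
})

test_that("oracle scenarios remove exactly one injected component each", {
  st <- smallStudy(seed = 19)
  sc <- oracleScenarios(st, "pm25")
  fl <- st@fields$pm25
  expect_identical(sc@fused$S1@values, fl$truth@values)
  for (nm in c(S2 = "em", S3 = "bc", S4 = "mt", S5 = "lu")) {
    s <- names(which(c(S2 = "em", S3 = "bc", S4 = "mt", S5 = "lu") == nm))[1]
    expect_equal(sc@fused[[s]]@values,
                 pmax(fl$ctm@values - fl$bias[[nm]], 0))
  }
})

test_that("configDays honors months and the per-month cap", {
  cfg <- syntheticConfig(daysPerMonth = 5L)
  dd <- configDays(cfg)
  expect_length(dd, 20)
  expect_identical(sort(unique(as.integer(format(dd, "%m")))),
                   c(1L, 4L, 7L, 10L))
  full <- configDays(syntheticConfig())
  expect_length(full, 31 + 30 + 31 + 31)
  expect_false(is.unsorted(full))
})
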
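# scenario bundle built from explicit matrices on a shared tiny domain
handScenarios <- function(cmaqM, fusedList, dom,
                          days = as.Date("2016-01-01") + seq_len(ncol(cmaqM)) - 1) {
  mk <- function(m) tinyField(m, dom, days = days)
  scenarioConcentrations(mk(cmaqM), lapply(fusedList, mk))
}

test_that("bias series reproduces hand-computed population-weighted deltas", {
  dom <- tinyDomain(1, 2)
  pop <- populationGrid(c(1, 3), c(0L, 2L))
  cmaq <- matrix(c(10, 20, 12, 24), 2, 2)   # pw: 17.5, 21
  s1 <- cmaq - 2                             # pw deltas all 2
  s2 <- matrix(c(8, 16, 10, 20), 2, 2)      # pw: 14, 17.5 -> deltas 3.5, 3.5
  sc <- handScenarios(cmaq, list(S1 = s1, S2 = s2, S3 = cmaq, S4 = cmaq,
                                 S5 = cmaq), dom)
  bs <- buildBiasSeries(sc, pop)
  expect_equal(bs$dTotal, c(2, 2))
  expect_equal(bs$dEM, c(3.5, 3.5))
  expect_equal(bs$dBC, c(0, 0))
  expect_identical(attr(bs, "scope"), "all")

  # S1 identical to the CTM: zero total bias everywhere
  sc0 <- handScenarios(cmaq, list(S1 = cmaq, S2 = s2, S3 = s1, S4 = s2,
                                  S5 = s1), dom)
  expect_equal(buildBiasSeries(sc0, pop)$dTotal, c(0, 0))

  # missing scenarios are an informative error
  scM <- handScenarios(cmaq, list(S1 = s1, S2 = s2), dom)
  expect_error(buildBiasSeries(scM, pop), "S3")
})

test_that("apportionment recovers an exactly linear relationship", {
  set.seed(41)
  nd <- 24
  mkBs <- function(dEM, dBC, dMT, dLU, dTotal) {
    bs <- data.frame(day = as.Date("2016-01-01") + seq_len(nd) - 1,
                     dTotal = dTotal, dEM = dEM, dBC = dBC, dMT = dMT,
                     dLU = dLU)
    attr(bs, "scope") <- "all"
    class(bs) <- c("biasSeries", "data.frame")
    bs
  }
  dEM <- rnorm(nd, 2); dBC <- rnorm(nd, 5); dMT <- rnorm(nd, 1)
  dLU <- rnorm(nd, 0.5)
  fit <- apportion(mkBs(dEM, dBC, dMT, dLU,
                        1 + 2 * dEM + 0.5 * dBC - 1.5 * dMT + 3 * dLU))
  expect_equal(unname(fit$coefficients),
               c(1, 2, 0.5, -1.5, 3), tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$contributions),
               c(2 * mean(dEM), 0.5 * mean(dBC), -1.5 * mean(dMT),
                 3 * mean(dLU)), tolerance = 1e-6)
  expect_equal(sum(fit$shares) +
                 abs(fit$unidentified) / (sum(abs(fit$contributions)) +
                                          abs(fit$unidentified)), 1,
               tolerance = 1e-9)

  # OLS residual identities: zero mean and orthogonal to every regressor
  fitN <- apportion(mkBs(dEM, dBC, dMT, dLU,
                         2 * dEM + 0.5 * dBC + rnorm(nd, 0, 0.3)))
  expect_lt(abs(mean(fitN$residuals)), 1e-9)
  for (v in list(dEM, dBC, dMT, dLU))
    expect_lt(abs(sum(fitN$residuals * v)), 1e-8)

  # degenerate designs fail loudly
  expect_error(apportion(mkBs(dEM, dEM, dMT, dLU, dEM)), "collinear")
  expect_error(apportion(mkBs(dEM, dBC, dMT, rep(2, nd), dEM)), "constant")
  short <- mkBs(dEM, dBC, dMT, dLU, dEM)[1:9, ]
  attr(short, "scope") <- "all"
  expect_error(apportion(short), "10 days")
})

test_that("oracle scenarios let apportionment recover the injected shares", {
  cfg <- syntheticConfig(seed = 43, nRows = 10L, nCols = 12L, nStations = 8L,
                         daysPerMonth = 8L)
  dm <- generateDomain(cfg)
  bl <- generatePredictors(cfg, dm$domain, dm$pop)
  for (p in c("pm25", "o3")) {
    fl <- generateFields(cfg, bl, p, noise = FALSE)
    sc <- scenarioConcentrations(fl$ctm, list(
      S1 = fl$truth,
      S2 = concentrationField(p, fl$ctm@values - fl$bias$em, bl@days, dm$domain),
      S3 = concentrationField(p, fl$ctm@values - fl$bias$bc, bl@days, dm$domain),
      S4 = concentrationField(p, fl$ctm@values - fl$bias$mt, bl@days, dm$domain),
      S5 = concentrationField(p, fl$ctm@values - fl$bias$lu, bl@days, dm$domain)))
    fit <- apportion(buildBiasSeries(sc, dm$pop))
    P <- dm$pop@population
    want <- vapply(fl$bias, function(b) mean(colSums(P * b) / sum(P)),
                   numeric(1))
    want <- abs(want) / sum(abs(want))
    expect_equal(unname(fit$shares), unname(want), tolerance = 0.01)
    expect_gt(fit$r2, 0.999)
  }
})

test_that("bias maps localize the components they are built from", {
  st <- smallStudy(seed = 45)
  sc <- oracleScenarios(st, "pm25")
  maps <- biasMap(sc)
  expect_named(maps, c("total", "em", "bc", "mt", "lu"))
  fl <- st@fields$pm25
  expect_equal(maps$em, rowMeans(fl$ctm@values -
                                 pmax(fl$ctm@values - fl$bias$em, 0)))

  # zero-bias study: every map is zero
  cfg0 <- syntheticConfig(seed = 45, nRows = 6L, nCols = 8L, nStations = 4L,
                          daysPerMonth = 4L,
                          gamma = c(em = 0, bc = 0, mt = 0, lu = 0),
                          ctmNoiseSd = c(pm25 = 0, o3 = 0))
  st0 <- simulateStudy(cfg0)
  maps0 <- biasMap(oracleScenarios(st0, "pm25"))
  for (m in maps0) expect_equal(m, rep(0, 48))

  # with a fit, component maps are scaled by the slopes
  fit <- apportion(buildBiasSeries(sc, st@pop))
  mapsF <- biasMap(sc, fit)
  expect_equal(mapsF$em, maps$em * unname(fit$coefficients[2]))
  expect_equal(mapsF$total, maps$total)
})

test_that("regional scoping restricts the series to the region's cells", {
  st <- smallStudy(seed = 47, nRegions = 2L)
  sc <- oracleScenarios(st, "pm25")
  bsAll <- buildBiasSeries(sc, st@pop)
  bsR1 <- buildBiasSeries(sc, st@pop, scope = "R1")
  expect_identical(attr(bsR1, "scope"), "R1")
  expect_false(isTRUE(all.equal(bsAll$dTotal, bsR1$dTotal)))
  # regional series recombine to the domain series by population weights
  bsR2 <- buildBiasSeries(sc, st@pop, scope = "R2")
  w <- vapply(c("R1", "R2"), function(r)
    sum(st@pop@population[regionIds(st@domain) == r]), numeric(1))
  w <- w / sum(w)
  expect_equal(w[1] * bsR1$dTotal + w[2] * bsR2$dTotal, bsAll$dTotal,
               tolerance = 1e-9)
})
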
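#' @include AllClasses.R metrics.R
NULL

## Measurement-model fusion: scenario-specific learners predicting the
## observed daily metric from the raw CTM value plus predictor blocks.
## S1 uses all blocks and is the fused baseline; S2-S5 each add a single
## block and isolate that block's share of the CTM bias.

.scenarioBlocks <- list(S1 = c("em", "bc", "mt", "lu"),
                        S2 = "em", S3 = "bc", S4 = "mt", S5 = "lu")

#' Scenario definition
#'
#' The five training scenarios: S1 (CTM + emissions + boundary conditions +
#' meteorology + land use), S2 (CTM + emissions), S3 (CTM + boundary
#' conditions), S4 (CTM + meteorology), S5 (CTM + land use). The raw CTM
#' feature is always included.
#'
#' @param name one of \code{"S1"} ... \code{"S5"}.
#' @return List with \code{name} and the included predictor \code{blocks}.
#' @export
scenarioSpec <- function(name = c("S1", "S2", "S3", "S4", "S5")) {
  name <- match.arg(name)
  list(name = name, blocks = .scenarioBlocks[[name]])
}

scenarioFeatures <- function(table, spec) {
  tags <- attr(table, "blocks")
  if (is.null(tags)) stop("table lacks the feature-block attribute")
  feats <- c("cmaq", unlist(tags[spec$blocks], use.names = FALSE))
  missing <- setdiff(feats, names(table))
  if (length(missing))
    stop("table is missing features for scenario ", spec$name, ": ",
         paste(missing, collapse = ", "))
  feats
}

rSquared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("target has zero variance; R^2 is undefined")
  1 - sum((obs - pred)^2) / sst
}

## small fixed hyperparameter grids searched by cross-validation
learnerGrid <- function(learner, p) {
  switch(learner,
    knn = data.frame(k = c(3L, 5L, 9L, 15L)),
    tree = data.frame(cp = c(0.01, 0.005, 0.001)),
    forest = data.frame(mtry = unique(pmax(1L, c(p %/% 3L, floor(sqrt(p)))))),
    boosted_trees = expand.grid(nrounds = 200L, max_depth = c(3L, 5L)),
    stop("unknown learner: ", learner))
}

fitLearnerOnce <- function(x, y, learner, par, seed) {
  switch(learner,
    knn = {
      ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
      xs <- scale(x, ctr, scl)
      list(kind = "knn", fit = caret::knnreg(as.data.frame(xs), y, k = par$k),
           center = ctr, scale = scl)
    },
    tree = {
      d <- data.frame(.y = y, x, check.names = FALSE)
      list(kind = "tree",
           fit = rpart::rpart(.y ~ ., data = d, method = "anova",
                              control = rpart::rpart.control(
                                cp = par$cp, minsplit = 10L, xval = 0L)))
    },
    forest = list(kind = "forest",
      fit = ranger::ranger(y = y, x = as.data.frame(x), num.trees = 300L,
                           mtry = min(par$mtry, ncol(x)), seed = seed,
                           num.threads = 1L)),
    boosted_trees = {
      dtr <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      list(kind = "boosted_trees",
           fit = xgboost::xgb.train(
             params = list(objective = "reg:squarederror", eta = 0.1,
                           max_depth = par$max_depth, subsample = 0.8,
                           nthread = 1L, seed = seed),
             data = dtr, nrounds = par$nrounds, verbose = 0))
    })
}

predictLearner <- function(model, x) {
  switch(model$kind,
    knn = as.numeric(predict(model$fit,
            as.data.frame(scale(x, model$center, model$scale)))),
    tree = as.numeric(predict(model$fit, as.data.frame(x))),
    forest = as.numeric(predict(model$fit, data = as.data.frame(x),
                                num.threads = 1L)$predictions),
    boosted_trees = as.numeric(predict(model$fit,
                                       xgboost::xgb.DMatrix(as.matrix(x)))))
}

#' Fit one fusion scenario with one learner
#'
#' Hyperparameters are chosen by k-fold cross-validation (default 10) on the
#' training partition only (lowest mean CV RMSE); the final model is refit on
#' the full training partition. Train and test R-squared are reported as
#' \eqn{1 - SS_{res}/SS_{tot}}, with the total sum of squares about the
#' respective partition mean. An overfitting flag marks fits whose train/test
#' R-squared gap exceeds \code{overfitGap}.
#'
#' @param table predictor table from \code{\link{assembleTable}}.
#' @param spec a \code{\link{scenarioSpec}} (or scenario name).
#' @param learner \code{"knn"}, \code{"tree"}, \code{"forest"} or
#'   \code{"boosted_trees"}.
#' @param split train/test indices from \code{\link{splitTable}}.
#' @param cvFolds number of cross-validation folds.
#' @param seed RNG seed controlling fold assignment and stochastic learners.
#' @param overfitGap train-minus-test R-squared gap beyond which the fit is
#'   flagged.
#' @return An object of class \code{"scenarioFit"}: the fitted model, the
#'   feature list, chosen hyperparameters, and a one-row \code{report}
#'   (learner, scenario, r2Train, r2Test, overfit).
#' @export
fitScenario <- function(table, spec = "S1", learner = "boosted_trees", split,
                        cvFolds = 10L, seed = 1L, overfitGap = 0.10) {
  if (is.character(spec)) spec <- scenarioSpec(spec)
  feats <- scenarioFeatures(table, spec)
  x <- as.matrix(table[, feats, drop = FALSE])
  y <- table$target
  xtr <- x[split$train, , drop = FALSE]; ytr <- y[split$train]
  xte <- x[split$test, , drop = FALSE]; yte <- y[split$test]
  if (sd(ytr) == 0) stop("target has zero variance; R^2 is undefined")

  grid <- learnerGrid(learner, ncol(x))
  set.seed(seed)
  fold <- sample(rep(seq_len(cvFolds), length.out = nrow(xtr)))
  cvRmse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(cvFolds), function(f) {
      hold <- fold == f
      m <- fitLearnerOnce(xtr[!hold, , drop = FALSE], ytr[!hold], learner,
                          grid[g, , drop = FALSE], seed)
      sqrt(mean((ytr[hold] - predictLearner(m, xtr[hold, , drop = FALSE]))^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- grid[which.min(cvRmse), , drop = FALSE]

  model <- fitLearnerOnce(xtr, ytr, learner, best, seed)
  report <- data.frame(
    learner = learner, scenario = spec$name,
    r2Train = rSquared(ytr, predictLearner(model, xtr)),
    r2Test = rSquared(yte, predictLearner(model, xte)))
  report$overfit <- (report$r2Train - report$r2Test) > overfitGap
  structure(list(model = model, learner = learner, spec = spec,
                 features = feats, params = best, report = report),
            class = "scenarioFit")
}

#' @export
print.scenarioFit <- function(x, ...) {
  cat(sprintf("scenarioFit %s/%s: R2 train %.3f, test %.3f%s\n",
              x$spec$name, x$learner, x$report$r2Train, x$report$r2Test,
              if (x$report$overfit) " (overfit)" else ""))
  invisible(x)
}

#' Predict a fused concentration field over the whole grid
#'
#' Applies a fitted scenario model to every cell-day of the domain (static
#' land use broadcast across days, boundary conditions across cells) and
#' clamps negative raw predictions to zero.
#'
#' @param fit a \code{"scenarioFit"}.
#' @param blocks the \linkS4class{PredictorBlocks}.
#' @param ctm the raw CTM field supplying the CTM feature, grid and days.
#' @return A fused \linkS4class{ConcentrationField}.
#' @export
predictGrid <- function(fit, blocks, ctm) {
  n <- nCells(ctm@domain); nd <- length(ctm@days)
  dayIdx <- match(ctm@days, blocks@days)
  if (anyNA(dayIdx)) stop("ctm days missing from the predictor blocks")
  cells <- rep(seq_len(n), times = nd)
  di <- rep(dayIdx, each = n)
  x <- cbind(cmaq = as.vector(ctm@values), featureRows(blocks, cells, di))
  x <- x[, fit$features, drop = FALSE]
  pred <- pmax(predictLearner(fit$model, x), 0)
  concentrationField(ctm@pollutant, matrix(pred, n, nd), ctm@days, ctm@domain)
}

#' Select the best learner from performance reports
#'
#' Keeps reports not flagged as overfitting and returns the learner with the
#' highest test R-squared. Exact ties are resolved by fewer predictor blocks,
#' then by the fixed precedence boosted_trees > forest > tree > knn.
#'
#' @param reports data.frame of report rows (from \code{fitScenario}
#'   reports, rbind-ed), with columns \code{learner}, \code{scenario},
#'   \code{r2Test}, \code{overfit}.
#' @return The selected learner name.
#' @export
selectBest <- function(reports) {
  reports <- as.data.frame(reports)
  ok <- reports[!reports$overfit, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("all candidate fits are flagged as overfitting; ",
         "no learner is selectable (gaps: ",
         paste(sprintf("%s=%.2f", reports$learner,
                       reports$r2Train - reports$r2Test), collapse = ", "), ")")
  nBlocks <- lengths(.scenarioBlocks)[ok$scenario]
  nBlocks[is.na(nBlocks)] <- 4L
  prec <- match(ok$learner, c("boosted_trees", "forest", "tree", "knn"))
  ord <- order(-ok$r2Test, nBlocks, prec)
  ok$learner[ord[1L]]
}

#' Fit all scenarios and build the fused field bundle
#'
#' Runs \code{\link{fitScenario}} and \code{\link{predictGrid}} for each
#' requested scenario with a single learner.
#'
#' @param table predictor table.
#' @param split train/test split.
#' @param blocks predictor blocks.
#' @param ctm raw CTM field.
#' @param learner learner name.
#' @param scenarios scenario names to fit (default all five).
#' @param cvFolds,seed,overfitGap passed to \code{\link{fitScenario}}.
#' @return List with \code{fits} (per scenario), \code{reports} (combined
#'   data.frame) and \code{sc} (a \linkS4class{ScenarioConcentrations}).
#' @export
fuseScenarios <- function(table, split, blocks, ctm,
                          learner = "boosted_trees",
                          scenarios = c("S1", "S2", "S3", "S4", "S5"),
                          cvFolds = 10L, seed = 1L, overfitGap = 0.10) {
  fits <- lapply(scenarios, function(s)
    fitScenario(table, s, learner, split, cvFolds, seed, overfitGap))
  names(fits) <- scenarios
  fused <- lapply(fits, predictGrid, blocks = blocks, ctm = ctm)
  list(fits = fits,
       reports = do.call(rbind, lapply(fits, `[[`, "report")),
       sc = scenarioConcentrations(ctm, fused))
}
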
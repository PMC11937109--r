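#' @include io.R fusion.R apportion.R health.R
NULL

#' Run the end-to-end fusion / apportionment / burden pipeline
#'
#' Executes the full flow for each configured pollutant: simulate the study,
#' compute station daily metrics, assemble and split the predictor table, fit
#' the fusion scenarios (choosing among candidate learners by S1 test
#' performance when several are configured), predict fused fields over the
#' grid, apportion the CTM bias per region, and tabulate premature deaths,
#' improvement ratios and the source-by-risk sensitivity matrix. All outputs
#' are written as CSV plus a JSON manifest; a rerun with the same
#' configuration reproduces the CSVs byte for byte.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @param stages last stage to run: \code{"simulate"}, \code{"metrics"},
#'   \code{"fuse"}, \code{"apportion"} or \code{"burden"} (default: all).
#' @param study optionally, a pre-built \linkS4class{SyntheticStudy} to use
#'   instead of simulating from \code{cfg$synthetic}.
#' @return Invisibly, a list with the study, per-pollutant results
#'   (\code{table}, \code{split}, \code{fuse}, \code{apportionment},
#'   \code{deaths}, \code{sensitivity}) and the manifest.
#' @export
runPipeline <- function(cfg, stages = "burden", study = NULL) {
  order <- c("simulate", "metrics", "fuse", "apportion", "burden")
  level <- match(match.arg(stages, order), order)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)

  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  if (is.null(study))
    study <- withStage("simulate", {
      sargs <- cfg$synthetic
      if (is.null(sargs$seed)) sargs$seed <- cfg$seed
      simulateStudy(do.call(syntheticConfig, sargs))
    })
  writeStudy(study, file.path(cfg$outDir, "study"))

  results <- list()
  canApportion <- all(c("S1", "S2", "S3", "S4", "S5") %in% cfg$scenarios)
  if (!canApportion && level >= 4L)
    warning("scenarios S2-S5 incomplete: apportionment disabled, ",
            "running fused baseline only")

  if (level >= 2L) for (p in cfg$pollutants) {
    res <- list()
    fl <- study@fields[[p]]
    res$metrics <- withStage("metrics", stationDailyMetrics(study@net, p))
    res$table <- withStage("metrics",
      assembleTable(fl$ctm, study@blocks, study@net, p))
    res$split <- splitTable(res$table, seed = cfg$seed)
    write.csv(res$metrics,
              file.path(cfg$outDir, sprintf("metrics_%s.csv", p)),
              row.names = FALSE, quote = FALSE)

    if (level >= 3L) {
      res$fuse <- withStage("fuse", {
        learner <- cfg$learners
        cand <- NULL
        if (length(learner) > 1L) {
          cand <- do.call(rbind, lapply(learner, function(l)
            fitScenario(res$table, "S1", l, res$split, cfg$cvFolds,
                        cfg$seed)$report))
          learner <- selectBest(cand)
        }
        out <- fuseScenarios(res$table, res$split, study@blocks, fl$ctm,
                             learner, cfg$scenarios, cfg$cvFolds, cfg$seed)
        out$candidates <- cand
        out
      })
      write.csv(res$fuse$reports,
                file.path(cfg$outDir, sprintf("performance_%s.csv", p)),
                row.names = FALSE, quote = FALSE)
      for (s in names(res$fuse$sc@fused))
        writeFieldCsv(res$fuse$sc@fused[[s]],
                      file.path(cfg$outDir, sprintf("fused_%s_%s.csv", p, s)))
    }

    if (level >= 4L && canApportion) {
      res$apportionment <- withStage("apportion", {
        scopes <- c("all", study@domain@regionNames)
        rows <- lapply(scopes, function(sc) {
          fit <- apportion(buildBiasSeries(res$fuse$sc, study@pop, sc))
          data.frame(scope = sc, r2 = fit$r2,
                     beta0 = fit$coefficients[1],
                     t(fit$coefficients[-1]), t(fit$contributions),
                     t(fit$shares), conditionNumber = fit$conditionNumber,
                     check.names = FALSE)
        })
        out <- do.call(rbind, rows)
        names(out) <- c("scope", "r2", "beta0", "betaEM", "betaBC", "betaMT",
                        "betaLU", "contribEM", "contribBC", "contribMT",
                        "contribLU", "shareEM", "shareBC", "shareMT",
                        "shareLU", "conditionNumber")
        rownames(out) <- NULL
        out
      })
      write.csv(res$apportionment,
                file.path(cfg$outDir, sprintf("apportionment_%s.csv", p)),
                row.names = FALSE, quote = FALSE)
    }

    if (level >= 5L) {
      res <- withStage("burden", {
        paramsHet <- crfFromConfig(cfg, p)
        paramsAvg <- averageRisk(paramsHet, study@pop)
        obsField <- exposureFromObservations(res$metrics, study@net, p)
        res$deaths <- scenarioDeathsTable(res$fuse$sc, obsField, study@pop,
                                          paramsHet)
        res$sensitivity <- sensitivityMatrix(
          list(observation = obsField, cmaq = res$fuse$sc@cmaq,
               mmf = res$fuse$sc@fused$S1),
          study@pop, paramsAvg, paramsHet)
        res
      })
      write.csv(res$deaths,
                file.path(cfg$outDir, sprintf("deaths_%s.csv", p)),
                row.names = FALSE, quote = FALSE)
      write.csv(res$sensitivity,
                file.path(cfg$outDir, sprintf("sensitivity_%s.csv", p)),
                row.names = FALSE, quote = FALSE)
    }
    results[[p]] <- res
  }

  cfgJson <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  manifest <- list(
    package = "mlmmf",
    version = as.character(utils::packageVersion("mlmmf")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    configHash = unname(tools::md5sum(tmp)),
    config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(study = study, results = results, manifest = manifest))
}
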
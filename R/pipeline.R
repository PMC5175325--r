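#' Run the index-construction pipeline end to end
#'
#' Orchestrates simulate -> assemble -> fit -> summarize (and optionally
#' compare) for one index, writing every artifact as CSV plus a run manifest.
#' A single master seed governs the whole run; each stage draws its own seed
#' deterministically from it, so identical config + seed reproduce
#' byte-identical CSV outputs.
#'
#' Config keys (YAML file or named list; flags in the shipped runner script
#' override them): \code{index}, \code{variant}, \code{stages} (subset of
#' simulate/assemble/fit/summarize/compare or \code{"all"}),
#' \code{survey_csv} (input for assemble when not simulating), \code{seed},
#' \code{out_dir}, \code{iterations}, \code{burnin}, \code{thin},
#' \code{missing_rate}, \code{n_countries}, \code{flag_threshold},
#' \code{anchor_item}, \code{compare_with} (country-score CSV of another run,
#' enables the compare stage).
#'
#' @param config path to a YAML config file, or a named list.
#' @param seed optional master seed overriding the config's.
#' @param outDir optional output directory overriding the config's.
#' @param verbose log one line per stage.
#' @return the run manifest (named list), invisibly; written as
#'   \code{manifest.yaml} in the output directory.
#' @export
runPipeline <- function(config, seed = NULL, outDir = NULL, verbose = TRUE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file path or a list",
                          call. = FALSE)
  defaults <- list(index = "infrastructure", variant = "regular",
                   stages = "all", survey_csv = NULL, seed = 1L,
                   out_dir = "pipeline_run", iterations = 4000L,
                   burnin = 1000L, thin = 3L, missing_rate = 0.05,
                   n_countries = 78L, flag_threshold = 0.10,
                   anchor_item = NULL, compare_with = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(defaults, cfg)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outDir)) cfg$out_dir <- outDir
  if (!cfg$index %in% .INDEX_NAMES)
    stop("unknown index name: ", cfg$index, call. = FALSE)
  if (!cfg$variant %in% c("regular", "annual"))
    stop("unknown inspection variant: ", cfg$variant, call. = FALSE)
  allStages <- c("simulate", "assemble", "fit", "summarize", "compare")
  stages <- if (identical(cfg$stages, "all")) {
    c("simulate", "assemble", "fit", "summarize",
      if (!is.null(cfg$compare_with)) "compare")
  } else {
    bad <- setdiff(cfg$stages, allStages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    allStages[allStages %in% cfg$stages]
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  set.seed(cfg$seed)
  stageSeeds <- sample.int(.Machine$integer.max - 1L, length(allStages))
  names(stageSeeds) <- allStages

  manifest <- list(package = "pharmRegIRT",
                   version = as.character(packageVersion("pharmRegIRT")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   config = cfg[setdiff(names(cfg), "stages")],
                   stages = stages, stage_seeds = as.list(stageSeeds),
                   inputs = list(), outputs = list(), warnings = list())
  registry <- loadRegistry()
  responses <- NULL
  draws <- NULL
  summary <- NULL

  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    if (verbose)
      message(sprintf("[%s] done in %.1fs", name,
                      proc.time()[["elapsed"]] - t0))
    res
  }

  if ("simulate" %in% stages) {
    sim <- runStage("simulate", function() {
      sim <- paperlikeScenario(cfg$index, seed = stageSeeds[["simulate"]],
                               N = cfg$n_countries,
                               missingRate = cfg$missing_rate)
      surveyPath <- file.path(cfg$out_dir, "survey.csv")
      writeSurveyCSV(sim$responses, surveyPath)
      truthPaths <- writeTruthCSV(sim$truth, file.path(cfg$out_dir, "truth"))
      manifest$outputs$survey <<- surveyPath
      manifest$outputs$truth_items <<- truthPaths[1]
      manifest$outputs$truth_countries <<- truthPaths[2]
      sim
    })
    responses <- sim$responses
  }

  if ("assemble" %in% stages) {
    responses <- runStage("assemble", function() {
      raw <- if (!is.null(cfg$survey_csv) && !"simulate" %in% stages) {
        manifest$inputs$survey_csv <<- cfg$survey_csv
        manifest$inputs$survey_fingerprint <<-
          .fnv1a(readLines(cfg$survey_csv, warn = FALSE))
        readSurveyCSV(cfg$survey_csv)
      } else if (!is.null(responses)) {
        readSurveyCSV(file.path(cfg$out_dir, "survey.csv"))
      } else stop("no survey input: set survey_csv or run the simulate stage")
      assembleResponses(raw, registry, cfg$index, cfg$variant)
    })
  }
  if (is.null(responses) && any(c("fit", "summarize") %in% stages))
    stop("fit/summarize need responses: run simulate/assemble first",
         call. = FALSE)

  if ("fit" %in% stages) {
    draws <- runStage("fit", function() {
      mc <- ModelConfig(
        anchorItem = if (is.null(cfg$anchor_item)) defaultAnchor(cfg$index)
                     else cfg$anchor_item,
        nBurnin = cfg$burnin, nIterations = cfg$iterations,
        thin = cfg$thin, seed = stageSeeds[["fit"]])
      d <- fitIRT(responses, mc)
      manifest$inputs$data_fingerprint <<- d@dataFingerprint
      for (block in c("lambda", "alpha", "phi")) {
        dm <- slot(d, block)
        long <- data.frame(draw = rep(seq_len(nrow(dm)), ncol(dm)),
                           parameter_id = rep(colnames(dm),
                                              each = nrow(dm)),
                           value = as.vector(dm))
        p <- file.path(cfg$out_dir, paste0("draws_", block, ".csv"))
        write.csv(long, p, row.names = FALSE, quote = FALSE)
        manifest$outputs[[paste0("draws_", block)]] <<- p
      }
      d
    })
  }

  if ("summarize" %in% stages) {
    if (is.null(draws)) stop("summarize needs the fit stage", call. = FALSE)
    summary <- runStage("summarize", function() {
      s <- summarizePosterior(draws, flagThreshold = cfg$flag_threshold)
      pItems <- file.path(cfg$out_dir, "item_summary.csv")
      pScores <- file.path(cfg$out_dir, "country_scores.csv")
      pDiag <- file.path(cfg$out_dir, "diagnostics.csv")
      it <- itemSummary(s)
      labels <- indexItems(registry, cfg$index)
      it$label <- labels$label[match(it$item_id, labels$item_id)]
      write.csv(format(it[, c("item_id", "label", "lambda_mean", "lambda_sd",
                              "alpha_mean", "alpha_sd", "lambda_pr_neg",
                              "flagged")], digits = 6, trim = TRUE),
                pItems, row.names = FALSE)
      write.csv(format(countryScores(s), digits = 6, trim = TRUE), pScores,
                row.names = FALSE, quote = FALSE)
      dg <- chainDiagnostics(draws, quiet = TRUE)
      nbad <- sum(abs(dg$geweke_z) > 3, na.rm = TRUE) + sum(dg$ess < 100)
      if (nbad > 0)
        manifest$warnings <<- c(manifest$warnings, sprintf(
          "%d chain(s) with |Geweke z| > 3 or ESS < 100", nbad))
      write.csv(format(dg, digits = 6, trim = TRUE), pDiag,
                row.names = FALSE, quote = FALSE)
      manifest$outputs$item_summary <<- pItems
      manifest$outputs$country_scores <<- pScores
      manifest$outputs$diagnostics <<- pDiag
      s
    })
  }

  if ("compare" %in% stages) {
    if (is.null(cfg$compare_with))
      stop("compare stage needs 'compare_with'", call. = FALSE)
    runStage("compare", function() {
      if (is.null(summary))
        stop("compare needs the summarize stage in the same run")
      other <- read.csv(cfg$compare_with, stringsAsFactors = FALSE)
      cmp <- compareIndices(summary, other,
                            indexNames = c(cfg$index, "other"))
      p <- file.path(cfg$out_dir, "comparison.csv")
      writeComparisonCSV(cmp, p)
      manifest$inputs$compare_with <<- cfg$compare_with
      manifest$outputs$comparison <<- p
      cmp
    })
  }

  manifestPath <- file.path(cfg$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifestPath)
  if (verbose)
    message("manifest written to ", manifestPath,
            if (length(manifest$warnings)) " (with warnings)" else "")
  invisible(manifest)
}
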
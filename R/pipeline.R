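#' Run the full assignment pipeline on a synthetic scenario
#'
#' Orchestrates every stage in order: simulate the study, convert all tissues
#' to epidermis currency, fit the carbon and nitrogen isoscapes, pool the
#' tissue covariance and assemble the per-cell covariance field, build
#' assignment surfaces for the calibration and assignment cohorts, validate
#' against the known-origin individuals, aggregate annual and overall
#' importance indices (count-, egg- and emergent-weighted), derive
#' emergence-rate surfaces and hotspot contribution tables, and run the
#' Friedman and Conover rank tests on the hotspot-by-year tables. When
#' `outDir` is given, the input CSVs, result tables, overall index rasters and
#' a run manifest are written there.
#'
#' The latent-truth sidecar produced by the simulator is never consumed here;
#' comparisons against generating parameters live in
#' [recoveryDiagnostics()].
#'
#' @param scenario a [Scenario-class]
#' @param outDir optional output directory
#' @param quiet suppress per-stage progress messages
#' @return a named list with every intermediate and final product
#' @export
runPipeline <- function(scenario, outDir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("stage simulate: generating synthetic study")
  sim <- simulateStudy(scenario, outDir = outDir)
  say(sprintf("  calibration n = %d, assignment n = %d (nests with fate: %d)",
              nrow(sim$calibration), nrow(sim$cohort),
              sum(!is.na(sim$cohort$clutch_size))))

  say("stage ingest: validating and converting to epidermis currency")
  calibration <- toEpidermis(
    validateSamples(sim$calibration, "calibration", grid = scenario@grid),
    scenario@conversion)
  cohort <- toEpidermis(validateSamples(sim$cohort, "assignment"),
                        scenario@conversion)
  cohort <- addNestOutcomes(cohort)

  say("stage isoscape: kriging d13C and d15N surfaces")
  isoC <- krigeSurface(calibration, scenario@grid, "C")
  isoN <- krigeSurface(calibration, scenario@grid, "N")

  say("stage covfield: pooling tissue covariance")
  tissue <- pooledTissueCovariance(calibration)
  covField <- buildCovField(tissue, isoC, isoN)

  say("stage assign: computing assignment surfaces")
  calStack <- assignSamples(calibration, isoC, isoN, covField)
  stack <- assignSamples(cohort, isoC, isoN, covField)

  say("stage validate: known-origin calibration check")
  validation <- validateCalibration(calStack, calibration)
  say(sprintf("  median normalized posterior at true cells = %.3f (Q1 %.3f)",
              validation$median, validation$q1))

  say("stage summarize: importance indices and hotspot tables")
  yearLabels <- as.character(scenario@years)
  countIdx <- lapply(scenario@years, function(y) foragingIndex(stack, y))
  names(countIdx) <- yearLabels
  eggs <- stats::setNames(cohort$clutch_size, cohort$id)
  emergents <- stats::setNames(cohort$emergents, cohort$id)
  fate <- cohort$id[!is.na(cohort$clutch_size)]
  eggIdx <- emergentIdx <- list()
  for (y in scenario@years) {
    lab <- as.character(y)
    eggIdx[[lab]] <- suppressWarnings(
      weightedIndex(stack, eggs, y, weighting = "eggs"))
    emergentIdx[[lab]] <- suppressWarnings(
      weightedIndex(stack, emergents, y, weighting = "emergents"))
  }
  overall <- list(
    count = foragingIndex(stack),
    eggs = suppressWarnings(weightedIndex(stack, eggs, weighting = "eggs")),
    emergents = suppressWarnings(
      weightedIndex(stack, emergents, weighting = "emergents")))
  rateSurfaces <- lapply(yearLabels, function(lab)
    emergenceRateSurface(eggIdx[[lab]], emergentIdx[[lab]]))
  names(rateSurfaces) <- yearLabels

  femaleTable <- hotspotTable(countIdx, sim$hotspots, normalize = "by_n")
  shareTable <- hotspotTable(countIdx, sim$hotspots,
                             normalize = "by_hotspot_total")
  rateTable <- emergenceRateTable(eggIdx, emergentIdx, sim$hotspots)

  say("stage testrank: Friedman + Conover on the hotspot tables")
  tests <- list(
    female = list(friedman = friedmanRankTest(femaleTable),
                  posthoc = conoverPosthoc(femaleTable)),
    emergence = list(friedman = friedmanRankTest(rateTable),
                     posthoc = conoverPosthoc(rateTable)))

  result <- list(scenario = scenario, calibration = calibration,
                 cohort = cohort, isoC = isoC, isoN = isoN, tissue = tissue,
                 covField = covField, calibrationStack = calStack,
                 stack = stack, validation = validation,
                 countIndices = countIdx, eggIndices = eggIdx,
                 emergentIndices = emergentIdx, overall = overall,
                 rateSurfaces = rateSurfaces, femaleTable = femaleTable,
                 shareTable = shareTable, rateTable = rateTable,
                 tests = tests)
  if (!is.null(outDir)) writePipelineOutputs(result, outDir)
  result
}

writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeContributionTable(result$femaleTable,
                         file.path(outDir, "female_index_by_n.csv"))
  writeContributionTable(result$shareTable,
                         file.path(outDir, "female_index_shares.csv"))
  writeContributionTable(result$rateTable,
                         file.path(outDir, "emergence_rates.csv"))
  g <- result$stack@grid
  if (!is.null(result$overall)) {
    writeAsciiGrid(result$overall$count@values, g,
                   file.path(outDir, "foraging_index_overall.asc"))
    writeAsciiGrid(result$overall$emergents@values, g,
                   file.path(outDir, "emergent_index_overall.asc"))
  }
  utils::write.csv(
    data.frame(id = names(result$validation$values),
               posterior = unname(result$validation$values)),
    file.path(outDir, "calibration_validation.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(female = friedmanAsList(result$tests$female),
         emergence = friedmanAsList(result$tests$emergence)),
    file.path(outDir, "rank_tests.json"), auto_unbox = TRUE, digits = NA)
  writeManifest(result, outDir)
  invisible(outDir)
}

friedmanAsList <- function(t) {
  list(chisq = t$friedman@statistic, df = t$friedman@df,
       p = t$friedman@p.value,
       letters = as.list(t$posthoc@letters))
}

#' Write a run manifest
#'
#' Records the seed, package version, input-file checksums and per-stage
#' counts of a pipeline run. Reruns with identical inputs produce identical
#' manifests apart from the timestamp.
#'
#' @param result a [runPipeline()] result
#' @param outDir the output directory (must already hold the input CSVs)
#' @export
writeManifest <- function(result, outDir) {
  inputs <- sort(list.files(outDir, pattern = "\\.(csv|geojson)$",
                            full.names = TRUE))
  sums <- tools::md5sum(inputs)
  manifest <- list(
    package = "isoforage",
    version = as.character(utils::packageVersion("isoforage")),
    seed = if (!is.null(result$scenario)) result$scenario@seed
           else result$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(stats::setNames(unname(sums), basename(inputs))),
    counts = list(calibration = nrow(result$calibration),
                  assignment = nrow(result$cohort),
                  nests = sum(!is.na(result$cohort$clutch_size)),
                  cells = sum(result$stack@grid@mask),
                  surfaces = length(result$stack@ids)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Compare pipeline output against the generating scenario
#'
#' Truth-recovery diagnostics for synthetic studies: per-year hotspot
#' contribution shares against the generating mixture weights, and per-hotspot
#' emergence rates (egg-weighted annual means) against the generating
#' emergence probabilities.
#'
#' @param result a [runPipeline()] result
#' @param scenario the generating [Scenario-class]
#' @return list with `mixtureError` (year x hotspot), `rateError` (per
#'   hotspot), and their maxima
#' @export
recoveryDiagnostics <- function(result, scenario) {
  shares <- t(result$shareTable@values)          # years x hotspots
  mixErr <- shares - scenario@mixtures
  rates <- rowMeans(result$rateTable@values, na.rm = TRUE)
  rateErr <- rates - scenario@emergenceProb[names(rates)]
  list(mixtureError = mixErr, rateError = rateErr,
       maxMixtureError = max(abs(mixErr)),
       maxRateError = max(abs(rateErr)))
}

#' Read and validate a pipeline configuration file
#'
#' YAML configuration for file-driven runs. Required keys: `seed`,
#' `calibration` (CSV path), `samples` (CSV path or list of paths),
#' `hotspots` (GeoJSON path) and `grid` (with `lon_min`, `lon_max`, `lat_min`,
#' `lat_max`, `cell_size`). Optional: `conversion` (YAML of tissue
#' coefficients), `out_dir`. Schema violations fail before any computation.
#'
#' @param path YAML file
#' @return validated configuration list with a built `grid` [GridSpec-class]
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("seed", "calibration", "samples", "hotspots", "grid")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("schema error: configuration is missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  gk <- c("lon_min", "lon_max", "lat_min", "lat_max", "cell_size")
  gmiss <- setdiff(gk, names(cfg$grid))
  if (length(gmiss))
    stop("schema error: grid block is missing key(s): ",
         paste(gmiss, collapse = ", "), call. = FALSE)
  cfg$grid <- gridSpec(cfg$grid$lon_min, cfg$grid$lon_max, cfg$grid$lat_min,
                       cfg$grid$lat_max, cfg$grid$cell_size)
  cfg
}

#' Run the pipeline from files
#'
#' File-driven counterpart of [runPipeline()] for real (non-simulated) data:
#' reads calibration and assignment tables, hotspot polygons and an optional
#' conversion model, then executes the isoscape, covariance, assignment,
#' validation, summary and rank-test stages.
#'
#' @param config a list from [readPipelineConfig()]
#' @param quiet suppress progress messages
#' @return a named list of pipeline products (as [runPipeline()], minus the
#'   simulator fields)
#' @export
runPipelineFromFiles <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  conv <- if (!is.null(config$conversion))
    readConversionModel(config$conversion) else defaultConversionModel()
  say("stage ingest")
  calibration <- toEpidermis(
    readSamples(config$calibration, "calibration", grid = config$grid), conv)
  paths <- unlist(config$samples)
  cohort <- do.call(rbind, lapply(paths, readSamples, role = "assignment"))
  cohort <- addNestOutcomes(toEpidermis(validateSamples(cohort, "assignment"),
                                        conv))
  hotspots <- readHotspots(config$hotspots)
  say("stage isoscape")
  isoC <- krigeSurface(calibration, config$grid, "C")
  isoN <- krigeSurface(calibration, config$grid, "N")
  say("stage covfield")
  tissue <- pooledTissueCovariance(calibration)
  covField <- buildCovField(tissue, isoC, isoN)
  say("stage assign + validate")
  calStack <- assignSamples(calibration, isoC, isoN, covField)
  stack <- assignSamples(cohort, isoC, isoN, covField)
  validation <- validateCalibration(calStack, calibration)
  say("stage summarize + testrank")
  years <- sort(unique(cohort$year))
  countIdx <- lapply(years, function(y) foragingIndex(stack, y))
  names(countIdx) <- as.character(years)
  eggs <- stats::setNames(cohort$clutch_size, cohort$id)
  emergents <- stats::setNames(cohort$emergents, cohort$id)
  eggIdx <- emergentIdx <- list()
  for (y in years) {
    lab <- as.character(y)
    eggIdx[[lab]] <- suppressWarnings(
      weightedIndex(stack, eggs, y, weighting = "eggs"))
    emergentIdx[[lab]] <- suppressWarnings(
      weightedIndex(stack, emergents, y, weighting = "emergents"))
  }
  femaleTable <- hotspotTable(countIdx, hotspots, normalize = "by_n")
  shareTable <- hotspotTable(countIdx, hotspots,
                             normalize = "by_hotspot_total")
  rateTable <- emergenceRateTable(eggIdx, emergentIdx, hotspots)
  tests <- list(
    female = list(friedman = friedmanRankTest(femaleTable),
                  posthoc = conoverPosthoc(femaleTable)),
    emergence = list(friedman = friedmanRankTest(rateTable),
                     posthoc = conoverPosthoc(rateTable)))
  out <- list(calibration = calibration, cohort = cohort, isoC = isoC,
              isoN = isoN, tissue = tissue, covField = covField,
              calibrationStack = calStack, stack = stack,
              validation = validation, countIndices = countIdx,
              eggIndices = eggIdx, emergentIndices = emergentIdx,
              femaleTable = femaleTable, shareTable = shareTable,
              rateTable = rateTable, tests = tests)
  out$seed <- config$seed
  if (!is.null(config$out_dir)) writePipelineOutputs(out, config$out_dir)
  out
}
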
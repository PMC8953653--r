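#' @include AllClasses.R utils.R constructors.R
NULL

## Column registry per table schema. Unit tags are embedded in the column
## names so concentration/area columns cannot be silently mixed up.
.SCHEMAS <- list(
  calibration = list(required = c("level_ng_ml", "analyte_area", "is_area",
                                  "analyte", "batch"),
                     numeric = c("level_ng_ml", "analyte_area", "is_area")),
  qc_areas = list(required = c("batch", "level_label", "spike_ng_ml",
                               "replicate", "analyte", "analyte_area",
                               "is_area"),
                  numeric = c("spike_ng_ml", "replicate", "analyte_area",
                              "is_area")),
  qc_conc = list(required = c("batch", "level_label", "spike_ng_ml",
                              "replicate", "analyte", "conc_ng_ml"),
                 numeric = c("spike_ng_ml", "replicate", "conc_ng_ml")),
  recovery = list(required = c("lot", "level_label", "design_arm", "analyte",
                               "area"),
                  numeric = "area"),
  stability = list(required = c("subject", "condition", "day", "analyte",
                                "measured_conc"),
                   numeric = c("day", "measured_conc")),
  cohort = list(required = c("subject_id", "group", "conc_4b_ng_ml",
                             "conc_4a_ng_ml", "total_chol_mg_dl"),
                numeric = c("conc_4b_ng_ml", "conc_4a_ng_ml",
                            "total_chol_mg_dl"))
)

#' Read a validated assay table
#'
#' Reads a UTF-8 CSV and validates it against one of the package's table
#' schemas (column presence and numeric type). Schema violations name the
#' offending column; non-numeric values report the first offending line.
#'
#' @param path CSV file path
#' @param schema one of `"calibration"`, `"qc_areas"`, `"qc_conc"`,
#'   `"recovery"`, `"stability"`, `"cohort"`
#' @return validated `data.frame`
#' @export
readAssayTable <- function(path, schema) {
  schema <- match.arg(schema, names(.SCHEMAS))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("empty input file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("no data rows in ", path, call. = FALSE)
  sc <- .SCHEMAS[[schema]]
  miss <- setdiff(sc$required, names(df))
  if (length(miss))
    stop("schema '", schema, "': missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in sc$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data line ",
           bad[1L], call. = FALSE)
    df[[col]] <- v
  }
  message(sprintf("read %d rows from %s [schema %s]", nrow(df), path, schema))
  df
}

#' Write an assay table as UTF-8 CSV
#'
#' @param table `data.frame`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAssayTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunables of the simulate -> calibrate -> validate -> cohort pipeline
#' with their assay defaults: the 8-level calibration ladder, 1/x weighting
#' with LLOQ 0.5 ng/ml, 3 validation batches of sextuplicate QCs at spikes
#' 0 / 0.5 / 1.5 / 25 / 400 ng/ml, the 85–115% stability window, and the
#' three-group cohort with ANOVA+Dunnett / Kruskal-Wallis+Dunn endpoint
#' mapping at alpha 0.05.
#'
#' @param seed integer seed for the whole run
#' @return nested configuration list (YAML-serialisable)
#' @export
defaultPipelineConfig <- function(seed = 20220216L) {
  list(
    seed = as.integer(seed),
    synthetic = list(
      slopeRatio = 0.01, intercept = 0, cvProportional = 0.04,
      sdAdditive = 5e-4, endogenous4b = 39.3, endogenous4a = 6.9,
      isNominalArea = 1e5, isCorrelation = 0.8, betweenBatchCV = 0.05,
      matrixFactorPerLot = as.list(assayGroundTruth()@matrixFactorPerLot),
      recoveryFactorPerLot = as.list(assayGroundTruth()@recoveryFactorPerLot),
      cohort = list(
        n = list(healthy = 9L, CKD3_5 = 15L, CKD5D = 14L),
        mean4b = c(23.6, 31.2, 22.7), sd4b = c(7.4, 10.3, 6.7),
        mean4a = c(3.6, 5.9, 4.8), sd4a = c(0.9, 1.4, 0.9),
        meanTC = c(159.4, 195.6, 160.0), sdTC = c(38.9, 23.4, 39.6),
        family = "normal", correlation = 0)),
    calibration = list(levels = defaultCalibrationLevels(),
                       weighting = "1/x", lloq = 0.5),
    validation = list(spikes = as.list(defaultQCSpikes()),
                      nBatches = 3L, nReps = 6L,
                      stabilityWindow = c(85, 115)),
    cohort = list(control = "healthy", alpha = 0.05,
                  endpointTests = as.list(defaultEndpointTests()),
                  dunnAdjust = "none")
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [defaultPipelineConfig()] values.
#'
#' @param path YAML file path
#' @return validated configuration list
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultPipelineConfig(), user)
  validatePipelineConfig(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg configuration list
#' @return the configuration, invisibly corrected types
#' @export
validatePipelineConfig <- function(cfg) {
  sw <- unlist(cfg$validation$stabilityWindow)
  if (length(sw) != 2L || sw[1L] >= sw[2L])
    stop("stability window lower bound must be below upper bound", call. = FALSE)
  a <- cfg$cohort$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!cfg$calibration$weighting %in% c("1/x", "1/x^2", "none"))
    stop("unknown calibration weighting: ", cfg$calibration$weighting,
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.truthFromConfig <- function(cfg) {
  s <- cfg$synthetic
  assayGroundTruth(
    slopeRatio = s$slopeRatio, intercept = s$intercept,
    cvProportional = s$cvProportional, sdAdditive = s$sdAdditive,
    endogenous4b = s$endogenous4b, endogenous4a = s$endogenous4a,
    matrixFactorPerLot = unlist(s$matrixFactorPerLot),
    recoveryFactorPerLot = unlist(s$recoveryFactorPerLot),
    isNominalArea = s$isNominalArea, isCorrelation = s$isCorrelation,
    betweenBatchCV = s$betweenBatchCV, seed = cfg$seed)
}

.cohortSpecFromConfig <- function(cfg) {
  cs <- cfg$synthetic$cohort
  cohortSpec(n = unlist(cs$n), mean4b = cs$mean4b, sd4b = cs$sd4b,
             mean4a = cs$mean4a, sd4a = cs$sd4a,
             meanTC = cs$meanTC, sdTC = cs$sdTC,
             family = cs$family, correlation = cs$correlation,
             seed = cfg$seed)
}

#' Run the complete pipeline
#'
#' Executes simulate -> calibrate -> validate -> cohort in order and writes
#' the report bundle (CSV tables and a JSON run manifest with the seed and
#' a configuration hash) to `outDir`. The run is deterministic for a fixed
#' seed: the manifest alone suffices to regenerate every output.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or the
#'   path of a YAML configuration file
#' @param outDir output directory (created if needed)
#' @param seed optional seed overriding the configuration's
#' @return (invisibly) list with `calibration` (models),
#'   `validation` ([ValidationReport-class]), `cohort` (analysis list),
#'   `manifest`
#' @examples
#' \donttest{
#' bundle <- runPipeline(defaultPipelineConfig(seed = 1L), tempdir())
#' bundle$validation
#' }
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = ".",
                        seed = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- validatePipelineConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  tryCatch({
    truth <- .truthFromConfig(config)

    stage <- "simulate"
    calTables <- do.call(rbind, lapply(.ANALYTES, function(an)
      generateCalibrationRun(truth, levels = unlist(config$calibration$levels),
                             analyte = an,
                             seed = deriveSeed(config$seed, match(an, .ANALYTES)))))
    qcAreas <- generateValidationBatches(
      truth, nBatches = config$validation$nBatches,
      nReps = config$validation$nReps,
      spikes = unlist(config$validation$spikes),
      seed = deriveSeed(config$seed, 10L))
    recAreas <- generateRecoveryMatrixExperiment(
      truth, seed = deriveSeed(config$seed, 20L))
    stabSeries <- generateStabilitySeries(
      truth, seed = deriveSeed(config$seed, 30L))
    cohort <- generateCohort(.cohortSpecFromConfig(config),
                             seed = deriveSeed(config$seed, 40L))

    stage <- "calibrate"
    models <- fitCalibrationTable(calTables,
                                  weighting = config$calibration$weighting)

    stage <- "validate"
    qcConc <- backCalculateBatches(qcAreas, models)
    rm <- assessRecoveryMatrix(recAreas)
    stab <- stabilityAssessSeries(
      stabSeries, window = unlist(config$validation$stabilityWindow))
    report <- summarizeValidation(qcConc, recovery = rm$recovery,
                                  matrixEffect = rm$matrix_effect,
                                  stability = stab)

    stage <- "cohort"
    cohortRes <- runCohortAnalysis(
      cohort, control = config$cohort$control, alpha = config$cohort$alpha,
      endpointTests = unlist(config$cohort$endpointTests),
      dunnAdjust = config$cohort$dunnAdjust)

    stage <- "write"
    writeAssayTable(calTables, file.path(outDir, "calibration_areas.csv"))
    calCoef <- do.call(rbind, lapply(names(models), function(an) {
      m <- models[[an]]
      data.frame(analyte = an, intercept = m@intercept, slope = m@slope,
                 r2_weighted = m@rSquaredWeighted,
                 r2_unweighted = m@rSquaredUnweighted,
                 weighting = m@weighting, stringsAsFactors = FALSE)
    }))
    writeAssayTable(calCoef, file.path(outDir, "calibration_models.csv"))
    writeAssayTable(qcConc, file.path(outDir, "qc_concentrations.csv"))
    writeAssayTable(report@withinBatch, file.path(outDir, "validation_within_batch.csv"))
    writeAssayTable(report@batchToBatch, file.path(outDir, "validation_batch_to_batch.csv"))
    writeAssayTable(rm$recovery, file.path(outDir, "recovery.csv"))
    writeAssayTable(rm$matrix_effect, file.path(outDir, "matrix_effect.csv"))
    writeAssayTable(stab, file.path(outDir, "stability.csv"))
    writeAssayTable(cohort, file.path(outDir, "cohort.csv"))
    writeAssayTable(cohortRes$summary, file.path(outDir, "cohort_summary.csv"))
    cohortTests <- do.call(rbind, lapply(names(cohortRes$tests), function(ep) {
      tst <- cohortRes$tests[[ep]]
      data.frame(endpoint = ep, test = tst@testName,
                 statistic = tst@statistic, p_value = tst@pValue,
                 stringsAsFactors = FALSE)
    }))
    writeAssayTable(cohortTests, file.path(outDir, "cohort_tests.csv"))

    manifest <- list(
      package = "oxyquant",
      version = as.character(utils::packageVersion("oxyquant")),
      seed = config$seed,
      config_md5 = configHash(config),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      outputs = c("calibration_areas.csv", "calibration_models.csv",
                  "qc_concentrations.csv", "validation_within_batch.csv",
                  "validation_batch_to_batch.csv", "recovery.csv",
                  "matrix_effect.csv", "stability.csv", "cohort.csv",
                  "cohort_summary.csv", "cohort_tests.csv"),
      config = config)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(calibration = models, validation = report,
                   cohort = cohortRes, manifest = manifest))
  }, error = function(e) {
    ## persist a failure marker naming the stage; partial outputs remain
    writeLines(c(stage, conditionMessage(e)),
               file.path(outDir, "failed"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Hash of a configuration list
#'
#' MD5 of the canonical JSON serialisation; recorded in the run manifest so
#' a bundle can be traced to the exact configuration that produced it.
#'
#' @param cfg configuration list
#' @return character MD5 hash
#' @export
configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
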
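#' @include AllClasses.R utils.R constructors.R
NULL

#' Simulate a surrogate-matrix calibration run
#'
#' Generates analyte and internal-standard peak areas for one calibration
#' batch in analyte-free surrogate matrix (2% human serum albumin), one row
#' per calibrator level and replicate. The expected analyte/IS area ratio is
#' linear in concentration: `intercept + slope * level`; proportional noise
#' is shared (correlated) between analyte and IS areas, additive noise acts
#' on the analyte area in ratio units.
#'
#' @param truth an [AssayGroundTruth-class]
#' @param levels calibrator concentrations (ng/ml), strictly positive and
#'   sorted; default [defaultCalibrationLevels()]
#' @param nReplicates replicate injections per level (default 1)
#' @param analyte `"4b_OHC"` or `"4a_OHC"` (no endogenous signal is present
#'   in surrogate matrix, so the choice only labels the rows)
#' @param batch batch identifier stored in the output
#' @param seed integer seed; defaults to `truth@seed`
#' @return `data.frame` with columns `level_ng_ml`, `analyte_area`,
#'   `is_area`, `analyte`, `batch`
#' @examples
#' truth <- assayGroundTruth(cvProportional = 0, sdAdditive = 0)
#' run <- generateCalibrationRun(truth)
#' run$analyte_area / run$is_area   # exactly 0.01 * level
#' @export
generateCalibrationRun <- function(truth,
                                   levels = defaultCalibrationLevels(),
                                   nReplicates = 1L,
                                   analyte = "4b_OHC",
                                   batch = 1L,
                                   seed = truth@seed) {
  stopifnot(is(truth, "AssayGroundTruth"))
  validObject(truth)
  if (length(levels) == 0L) stop("empty calibrator level list", call. = FALSE)
  if (any(levels <= 0)) stop("calibrator levels must be strictly positive", call. = FALSE)
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be sorted, distinct", call. = FALSE)
  assertAnalytes(analyte)
  withSeed(seed, {
    lev <- rep(levels, each = nReplicates)
    n <- length(lev)
    fac <- ratioNoiseFactors(n, truth@cvProportional, truth@isCorrelation)
    isArea <- truth@isNominalArea * fac$is
    expected <- expectedRatio(truth, lev) * truth@isNominalArea
    anArea <- expected * fac$analyte +
      stats::rnorm(n, 0, truth@sdAdditive) * truth@isNominalArea
    data.frame(level_ng_ml = lev,
               analyte_area = anArea,
               is_area = isArea,
               analyte = analyte,
               batch = batch,
               stringsAsFactors = FALSE)
  })
}

.spikeLabels <- function(spikes) {
  if (!is.null(names(spikes)) && all(nzchar(names(spikes)))) return(names(spikes))
  ## unnamed: blank first (spike 0), then the standard QC ladder order
  lbl <- character(length(spikes))
  nonblank <- spikes > 0
  lbl[!nonblank] <- "endogenous"
  std <- c("LLOQ", "QCA", "QCB", "QCC")
  lbl[nonblank] <- std[seq_len(sum(nonblank))]
  lbl
}

#' Simulate a background-addition QC validation study
#'
#' Generates peak-area tables for `nBatches` validation batches, each with
#' blank (endogenous-only) and spiked QC samples in `nReps`-plicate. The
#' per-batch endogenous level varies around the global truth by
#' `truth@betweenBatchCV`; the nominal concentration of a spiked QC is that
#' batch's endogenous level plus the spike.
#'
#' @param truth an [AssayGroundTruth-class]
#' @param nBatches number of validation batches (>= 1; default 3)
#' @param nReps replicates per level per batch (>= 2; default 6)
#' @param spikes added concentrations (ng/ml) with 0 for the blank; default
#'   [defaultQCSpikes()] = 0 / 0.5 / 1.5 / 25 / 400
#' @param analytes which analytes to generate (default both)
#' @param bias multiplicative measurement bias applied to the expected
#'   concentration (1 = unbiased). Also used to emulate stress-test
#'   degradation (e.g. 0.95 for a 5% loss in freeze-thaw cycles).
#' @param seed integer seed; defaults to `truth@seed`
#' @return `data.frame` with columns `batch`, `level_label`, `spike_ng_ml`,
#'   `replicate`, `analyte`, `analyte_area`, `is_area`
#' @examples
#' qc <- generateValidationBatches(assayGroundTruth())
#' table(qc$level_label, qc$analyte)
#' @export
generateValidationBatches <- function(truth,
                                      nBatches = 3L,
                                      nReps = 6L,
                                      spikes = defaultQCSpikes(),
                                      analytes = .ANALYTES,
                                      bias = 1,
                                      seed = truth@seed) {
  stopifnot(is(truth, "AssayGroundTruth"))
  validObject(truth)
  if (nBatches < 1L) stop("nBatches must be >= 1", call. = FALSE)
  if (nReps < 2L) stop("nReps must be >= 2", call. = FALSE)
  if (any(spikes < 0)) stop("negative spike concentration", call. = FALSE)
  if (bias <= 0) stop("bias must be > 0", call. = FALSE)
  assertAnalytes(analytes)
  labels <- .spikeLabels(spikes)
  withSeed(seed, {
    out <- vector("list", length(analytes) * nBatches)
    k <- 0L
    for (an in analytes) {
      endo <- endogenousLevel(truth, an)
      for (b in seq_len(nBatches)) {
        endoBatch <- endo * (1 + stats::rnorm(1, 0, truth@betweenBatchCV))
        endoBatch <- max(endoBatch, 0)
        conc <- rep(endoBatch + spikes, each = nReps) * bias
        n <- length(conc)
        fac <- ratioNoiseFactors(n, truth@cvProportional, truth@isCorrelation)
        isArea <- truth@isNominalArea * fac$is
        anArea <- expectedRatio(truth, conc) * truth@isNominalArea * fac$analyte +
          stats::rnorm(n, 0, truth@sdAdditive) * truth@isNominalArea
        k <- k + 1L
        out[[k]] <- data.frame(
          batch = b,
          level_label = rep(labels, each = nReps),
          spike_ng_ml = rep(unname(spikes), each = nReps),
          replicate = rep(seq_len(nReps), times = length(spikes)),
          analyte = an,
          analyte_area = anArea,
          is_area = isArea,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate the recovery / matrix-effect experiment
#'
#' Three design arms per plasma lot and QC level, mirroring the classical
#' post-extraction-spike design:
#' \describe{
#'   \item{`pre_extraction_spike`}{plasma spiked before extraction; the spike
#'     experiences both the lot's extraction recovery and its matrix factor}
#'   \item{`post_extraction_spike`}{plasma spiked after extraction; the spike
#'     experiences the matrix factor only (100% of the analyte amount in an
#'     identical matrix)}
#'   \item{`neat_solution`}{matrix-free standard at 100%}
#' }
#' Because unadulterated plasma contains both analytes, the endogenous signal
#' (which always carries both factors) is added to the two plasma arms; with
#' `includeBlank = TRUE` (default) a `blank_plasma` arm of unspiked plasma is
#' emitted per lot so downstream estimators can subtract it. All arms of one
#' lot draw on a single pooled aliquot measured in the same run, so the
#' endogenous contribution is common to the lot's arms and blank subtraction
#' removes it exactly; only the spike contribution carries independent
#' injection noise.
#'
#' Each emitted area represents the mean of `nReps` replicate injections
#' (the noise SD scales with `1/sqrt(nReps)`), giving one row per
#' lot x level x arm.
#'
#' @param truth an [AssayGroundTruth-class]
#' @param nLots number of plasma lots (<= lots in the truth factor maps)
#' @param spikes QC spike levels (ng/ml), default QCA/QCB/QCC = 1.5/25/400
#' @param arms design arms to generate (default all three)
#' @param nReps replicate injections averaged into each area (default 6)
#' @param includeBlank also emit unspiked `blank_plasma` rows per lot
#' @param analytes which analytes to generate
#' @param seed integer seed; defaults to `truth@seed`
#' @return `data.frame` with columns `lot`, `level_label`, `design_arm`,
#'   `analyte`, `area`
#' @examples
#' rec <- generateRecoveryMatrixExperiment(assayGroundTruth())
#' assessRecoveryMatrix(rec)$recovery
#' @export
generateRecoveryMatrixExperiment <- function(truth,
                                             nLots = length(truth@recoveryFactorPerLot),
                                             spikes = defaultQCSpikes(FALSE)[-1L],
                                             arms = .DESIGN_ARMS,
                                             nReps = 6L,
                                             includeBlank = TRUE,
                                             analytes = .ANALYTES,
                                             seed = truth@seed) {
  stopifnot(is(truth, "AssayGroundTruth"))
  validObject(truth)
  if (nLots < 1L) stop("nLots must be >= 1", call. = FALSE)
  if (nLots > length(truth@recoveryFactorPerLot))
    stop("nLots exceeds the lots parameterised in the ground truth", call. = FALSE)
  bad <- setdiff(arms, .DESIGN_ARMS)
  if (length(bad))
    stop("unknown design_arm requested: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(spikes <= 0)) stop("recovery spikes must be positive", call. = FALSE)
  assertAnalytes(analytes)
  labels <- .spikeLabels(spikes)
  lots <- names(truth@recoveryFactorPerLot)[seq_len(nLots)]
  sdMean <- truth@cvProportional / sqrt(nReps)
  noisy <- function(x) x * (1 + stats::rnorm(length(x), 0, sdMean))
  withSeed(seed, {
    rows <- list()
    for (an in analytes) {
      endo <- endogenousLevel(truth, an)
      for (i in seq_len(nLots)) {
        m <- truth@matrixFactorPerLot[[lots[i]]]
        r <- truth@recoveryFactorPerLot[[lots[i]]]
        ## endogenous analyte is present pre-extraction: carries m and r.
        ## One pooled aliquot of the lot is shared by every arm in one run,
        ## so its measured contribution is common to all arms of the lot
        ## (blank subtraction then cancels it exactly).
        endoArea <- noisy(expectedRatio(truth, endo) * truth@isNominalArea * m * r)
        for (j in seq_along(spikes)) {
          neatArea <- expectedRatio(truth, unname(spikes[j])) * truth@isNominalArea
          spikeArea <- c(pre_extraction_spike = neatArea * m * r,
                         post_extraction_spike = neatArea * m,
                         neat_solution = neatArea)[arms]
          endoPart <- c(pre_extraction_spike = endoArea,
                        post_extraction_spike = endoArea,
                        neat_solution = 0)[arms]
          rows[[length(rows) + 1L]] <- data.frame(
            lot = lots[i], level_label = labels[j], design_arm = arms,
            analyte = an, area = noisy(unname(spikeArea)) + unname(endoPart),
            stringsAsFactors = FALSE)
        }
        if (includeBlank) {
          rows[[length(rows) + 1L]] <- data.frame(
            lot = lots[i], level_label = "blank", design_arm = "blank_plasma",
            analyte = an, area = endoArea, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Default storage-drift parameters
#'
#' Phenomenological dip-then-rise residual curves for plasma oxysterols
#' stored with or without air contact. Open tubes show a transient decrease
#' (depth `dip` centred at day `tDip` on a log-day scale) followed by an
#' autoxidative rise reaching `+rise` (fraction of the fresh level) at the
#' 30-day horizon; closed (safe-lock) tubes stay at 100%. The decrease
#' itself has no established mechanism; the curve is a descriptive stand-in
#' calibrated so that room-temperature open storage breaches the 85% bound
#' by day 2 and the 115% bound by day 30, with the 4 degC kinetics delayed.
#'
#' @return named list of per-condition parameter lists with elements
#'   `dip`, `tDip`, `logWidth`, `rise`, `tLag`, `riseExp`, `tRef`
#' @export
stabilityDriftDefaults <- function() {
  list(
    open_RT  = list(dip = 0.25, tDip = 2, logWidth = 0.6,
                    rise = 0.80, tLag = 4,  riseExp = 1.5, tRef = 30),
    open_4C  = list(dip = 0.20, tDip = 7, logWidth = 0.6,
                    rise = 0.50, tLag = 10, riseExp = 1.5, tRef = 30),
    closed_RT = list(dip = 0, tDip = 1, logWidth = 0.6,
                     rise = 0, tLag = 14, riseExp = 1.5, tRef = 30),
    closed_4C = list(dip = 0, tDip = 1, logWidth = 0.6,
                     rise = 0, tLag = 14, riseExp = 1.5, tRef = 30)
  )
}

#' Evaluate a storage-drift residual curve
#'
#' @param day storage time (days, >= 0)
#' @param params one per-condition element of [stabilityDriftDefaults()]
#' @return expected residual as a fraction of the fresh level (1 = 100%)
#' @examples
#' stabilityResidualCurve(2, stabilityDriftDefaults()$open_RT)   # < 0.85
#' stabilityResidualCurve(30, stabilityDriftDefaults()$open_RT)  # > 1.15
#' @export
stabilityResidualCurve <- function(day, params) {
  stopifnot(all(day >= 0))
  dip <- ifelse(day > 0,
                params$dip * exp(-(log(pmax(day, 1e-12) / params$tDip))^2 /
                                   (2 * params$logWidth^2)),
                0)
  rise <- params$rise *
    (pmax(0, day - params$tLag) / (params$tRef - params$tLag))^params$riseExp
  1 - dip + rise
}

#' Simulate a storage-stability time series
#'
#' Generates per-subject measured concentrations for plasma aliquots stored
#' under combinations of tube type (open vs safe-lock) and temperature
#' (room temperature vs 4 degC), following the per-condition residual curves
#' in `drift`. Day-0 rows (the freshly measured reference for each subject,
#' repeated per condition) are always included.
#'
#' @param truth an [AssayGroundTruth-class]
#' @param conditions subset of `open_RT`, `open_4C`, `closed_RT`, `closed_4C`
#' @param days storage days, strictly increasing, all > 0 (default
#'   1, 2, 7, 14, 30)
#' @param nSubjects number of plasma donors (default 6)
#' @param drift per-condition curve parameters; default
#'   [stabilityDriftDefaults()]
#' @param betweenSubjectCV CV of the per-subject endogenous level around the
#'   global truth (default 0.15)
#' @param analytes which analytes to generate
#' @param seed integer seed; defaults to `truth@seed`
#' @return `data.frame` with columns `subject`, `condition`, `day`,
#'   `analyte`, `measured_conc`
#' @examples
#' ss <- generateStabilitySeries(assayGroundTruth())
#' stabilityAssessSeries(ss)
#' @export
generateStabilitySeries <- function(truth,
                                    conditions = .STAB_CONDITIONS,
                                    days = c(1, 2, 7, 14, 30),
                                    nSubjects = 6L,
                                    drift = stabilityDriftDefaults(),
                                    betweenSubjectCV = 0.15,
                                    analytes = .ANALYTES,
                                    seed = truth@seed) {
  stopifnot(is(truth, "AssayGroundTruth"))
  validObject(truth)
  bad <- setdiff(conditions, .STAB_CONDITIONS)
  if (length(bad))
    stop("unknown storage condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(days) == 0L || any(days <= 0))
    stop("days must be positive (day 0 is added automatically)", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE))
    stop("days must be strictly increasing", call. = FALSE)
  if (nSubjects < 1L) stop("nSubjects must be >= 1", call. = FALSE)
  missingPar <- setdiff(conditions, names(drift))
  if (length(missingPar))
    stop("drift parameters missing for: ", paste(missingPar, collapse = ", "),
         call. = FALSE)
  assertAnalytes(analytes)
  allDays <- c(0, days)
  withSeed(seed, {
    rows <- list()
    for (an in analytes) {
      endo <- endogenousLevel(truth, an)
      subjEndo <- rtruncnorm0(nSubjects, endo, betweenSubjectCV * endo)
      for (cond in conditions) {
        curve <- stabilityResidualCurve(allDays, drift[[cond]])
        for (s in seq_len(nSubjects)) {
          expConc <- subjEndo[s] * curve
          meas <- expConc * (1 + stats::rnorm(length(expConc), 0,
                                              truth@cvProportional))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sprintf("S%02d", s), condition = cond, day = allDays,
            analyte = an, measured_conc = meas, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a three-group clinical cohort
#'
#' Draws per-subject plasma 4beta-OHC, 4alpha-OHC and total cholesterol for
#' each group of a [CohortSpec-class]. The `normal` family is truncated at
#' zero (negligible for the default means, several SDs above zero); the
#' `lognormal` family is moment-matched to the specified mean and SD.
#' A common within-subject correlation couples the three measures through a
#' Gaussian copula.
#'
#' @param spec a [CohortSpec-class]
#' @param seed integer seed; defaults to `spec@seed`
#' @return `data.frame` with columns `subject_id`, `group`,
#'   `conc_4b_ng_ml`, `conc_4a_ng_ml`, `total_chol_mg_dl`
#' @examples
#' cohort <- generateCohort(cohortSpec())
#' table(cohort$group)   # 9 / 15 / 14
#' @export
generateCohort <- function(spec, seed = spec@seed) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  drawGroup <- function(n, mu, sd, R) {
    ## one correlated draw of (4b, 4a, TC) per subject via Gaussian copula
    z <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(R)
    if (spec@family == "normal") {
      sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
    } else {
      x <- vapply(1:3, function(j) {
        if (sd[j] == 0) return(rep(mu[j], n))
        s2 <- log(1 + (sd[j] / mu[j])^2)
        exp(log(mu[j]) - s2 / 2 + sqrt(s2) * z[, j])
      }, numeric(n))
      matrix(x, n, 3)
    }
  }
  withSeed(seed, {
    rows <- list()
    for (g in seq_along(spec@n)) {
      n <- spec@n[g]
      mu <- c(spec@mean4b[g], spec@mean4a[g], spec@meanTC[g])
      sd <- c(spec@sd4b[g], spec@sd4a[g], spec@sdTC[g])
      R <- matrix(spec@correlation, 3, 3); diag(R) <- 1
      x <- drawGroup(n, mu, sd, R)
      ## truncation at zero by whole-subject rejection (exact; negligible
      ## rejection rate at the default means, all >= 4 SDs above zero)
      bad <- which(rowSums(x <= 0) > 0)
      while (length(bad)) {
        x[bad, ] <- drawGroup(length(bad), mu, sd, R)
        bad <- bad[rowSums(x[bad, , drop = FALSE] <= 0) > 0]
      }
      rows[[g]] <- data.frame(
        subject_id = sprintf("%s_%02d", names(spec@n)[g], seq_len(n)),
        group = names(spec@n)[g],
        conc_4b_ng_ml = x[, 1L],
        conc_4a_ng_ml = x[, 2L],
        total_chol_mg_dl = x[, 3L],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
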
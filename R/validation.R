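#' @include AllClasses.R utils.R
NULL

#' Per-batch endogenous level from blank QCs
#'
#' Arithmetic mean of the measured concentrations of the blank (unspiked)
#' QC replicates of one batch. For an endogenous analyte this mean is the
#' batch's reference point: every background-addition nominal concentration
#' in the same batch is `endogenous + spike`.
#'
#' @param blanks measured blank-QC concentrations (ng/ml), >= 2 replicates
#' @return mean endogenous concentration (ng/ml)
#' @examples
#' estimateEndogenous(c(39.8, 40.4, 40.1, 40.2, 39.9, 40.2))
#' @export
estimateEndogenous <- function(blanks) {
  if (length(blanks) == 0L) stop("no blank replicates supplied", call. = FALSE)
  if (length(blanks) < 2L) stop("need >= 2 blank replicates", call. = FALSE)
  mean(blanks)
}

#' Background-addition accuracy
#'
#' Accuracy of an endogenous-analyte QC as a percentage of the measured
#' concentration to the nominal concentration, where the nominal is the
#' batch's endogenous mean plus the spiked amount:
#' `100 * measured / (endogenous + spike)`.
#'
#' @param measuredMean measured mean concentration (ng/ml)
#' @param endogenousMean the batch's endogenous mean (ng/ml, >= 0)
#' @param spike the added concentration (ng/ml, > 0)
#' @return accuracy in percent (full precision; round to 1 decimal for
#'   reporting)
#' @examples
#' accuracyBackgroundAddition(67.0, 40.1, 25)    # 102.9...
#' accuracyBackgroundAddition(402.4, 37.1, 400)  # 92.1...
#' @export
accuracyBackgroundAddition <- function(measuredMean, endogenousMean, spike) {
  if (any(spike <= 0)) stop("spike must be > 0 for a spiked QC", call. = FALSE)
  if (any(endogenousMean < 0)) stop("endogenous mean must be >= 0", call. = FALSE)
  nominal <- endogenousMean + spike
  if (any(nominal <= 0)) stop("nonpositive nominal concentration", call. = FALSE)
  100 * measuredMean / nominal
}

#' Precision as percent coefficient of variation
#'
#' `100 * sd / mean` with the sample SD (n-1 denominator).
#'
#' @param values replicate measured concentrations, >= 2 values
#' @return %CV
#' @examples
#' precisionCV(c(9, 11))   # 14.28...
#' @export
precisionCV <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values for a CV", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Apparent extraction recovery per lot
#'
#' `100 * pre / post` for paired pre-extraction-spiked and
#' post-extraction-spiked areas of the same plasma lot, plus the mean and
#' (min-max) range across lots. The post-extraction spike represents 100%
#' of the analyte amount in an identical matrix, so the ratio isolates the
#' extraction step.
#'
#' @param pre pre-extraction-spike peak areas, one per lot (endogenous
#'   signal already subtracted if applicable)
#' @param post post-extraction-spike peak areas, paired by lot
#' @return list with `per_lot` (%), `mean`, `min`, `max`
#' @examples
#' apparentRecovery(c(92, 90), c(100, 100))$mean   # 91
#' @export
apparentRecovery <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post areas must be paired by lot", call. = FALSE)
  if (length(pre) < 1L) stop("need >= 1 lot", call. = FALSE)
  if (any(post == 0)) stop("zero post-extraction-spike area", call. = FALSE)
  pct <- 100 * pre / post
  list(per_lot = pct, mean = mean(pct), min = min(pct), max = max(pct))
}

#' Matrix effect per lot
#'
#' `100 * post / neat` for paired post-extraction-spiked plasma and neat
#' (matrix-free) solution areas; values below 100% indicate ionisation
#' suppression, above 100% enhancement.
#'
#' @param post post-extraction-spike peak areas per lot (endogenous signal
#'   already subtracted if applicable)
#' @param neat neat-solution areas (recycled if a single reference)
#' @return list with `per_lot` (%), `mean`, `min`, `max`
#' @examples
#' matrixEffect(c(110, 108), 100)$mean   # 109
#' @export
matrixEffect <- function(post, neat) {
  if (length(neat) == 1L) neat <- rep(neat, length(post))
  if (length(post) != length(neat))
    stop("post and neat areas must be paired", call. = FALSE)
  if (any(neat == 0)) stop("zero neat-solution area", call. = FALSE)
  pct <- 100 * post / neat
  list(per_lot = pct, mean = mean(pct), min = min(pct), max = max(pct))
}

#' Recovery and matrix effect from a design-arm area table
#'
#' Wrangles the output of [generateRecoveryMatrixExperiment()] (or a
#' measured table with the same columns) into per-lot, per-level apparent
#' recovery and matrix effect. When `blank_plasma` rows are present and
#' `subtractBlank = TRUE`, each lot's blank area (the endogenous signal) is
#' subtracted from both plasma arms before ratioing — necessary for an
#' endogenous analyte, whose signal is present in every plasma arm.
#'
#' @param armTable `data.frame` with columns `lot`, `level_label`,
#'   `design_arm`, `analyte`, `area`
#' @param subtractBlank subtract the per-lot blank-plasma area (default
#'   `TRUE` when blank rows are present)
#' @return list of two `data.frame`s, `recovery` and `matrix_effect`, each
#'   with per-lot percentages and per-level `mean_pct`, `min_pct`, `max_pct`
#' @export
assessRecoveryMatrix <- function(armTable,
                                 subtractBlank = any(armTable$design_arm == "blank_plasma")) {
  need <- c("lot", "level_label", "design_arm", "analyte", "area")
  miss <- setdiff(need, names(armTable))
  if (length(miss))
    stop("arm table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  recRows <- list(); meRows <- list()
  for (an in unique(armTable$analyte)) {
    d <- armTable[armTable$analyte == an, ]
    blanks <- d[d$design_arm == "blank_plasma", ]
    blankByLot <- if (nrow(blanks))
      tapply(blanks$area, blanks$lot, mean) else NULL
    if (subtractBlank && is.null(blankByLot))
      stop("subtractBlank = TRUE but no blank_plasma rows present", call. = FALSE)
    spiked <- d[d$design_arm != "blank_plasma", ]
    for (lev in unique(spiked$level_label)) {
      dl <- spiked[spiked$level_label == lev, ]
      lots <- sort(unique(dl$lot))
      getArm <- function(arm) {
        a <- dl[dl$design_arm == arm, ]
        a <- a[match(lots, a$lot), ]
        a$area
      }
      pre <- getArm("pre_extraction_spike")
      post <- getArm("post_extraction_spike")
      neat <- getArm("neat_solution")
      if (subtractBlank) {
        bl <- as.numeric(blankByLot[lots])
        pre <- pre - bl
        post <- post - bl
      }
      if (!anyNA(pre) && !anyNA(post)) {
        rec <- apparentRecovery(pre, post)
        recRows[[length(recRows) + 1L]] <- data.frame(
          analyte = an, level_label = lev, lot = lots,
          recovery_pct = rec$per_lot, mean_pct = rec$mean,
          min_pct = rec$min, max_pct = rec$max, stringsAsFactors = FALSE)
      }
      if (!anyNA(post) && !anyNA(neat)) {
        me <- matrixEffect(post, neat)
        meRows[[length(meRows) + 1L]] <- data.frame(
          analyte = an, level_label = lev, lot = lots,
          matrix_effect_pct = me$per_lot, mean_pct = me$mean,
          min_pct = me$min, max_pct = me$max, stringsAsFactors = FALSE)
      }
    }
  }
  list(recovery = if (length(recRows)) do.call(rbind, recRows) else data.frame(),
       matrix_effect = if (length(meRows)) do.call(rbind, meRows) else data.frame())
}

#' Classify storage stability from a residual percentage
#'
#' `residual = 100 * measured / reference`; the sample is stable when the
#' residual lies within the acceptance window (85–115% by default, bounds
#' inclusive).
#'
#' @param measured measured concentration(s) (ng/ml)
#' @param reference fresh (day-0) reference concentration (ng/ml, > 0)
#' @param window acceptance window in percent, default `c(85, 115)`
#' @return `data.frame` with columns `residual_pct`, `stable`
#' @examples
#' stabilityAssess(c(84.9, 100, 115), 100)
#' @export
stabilityAssess <- function(measured, reference, window = c(85, 115)) {
  if (any(reference <= 0)) stop("reference must be > 0", call. = FALSE)
  if (window[1L] >= window[2L])
    stop("stability window lower bound must be below upper bound", call. = FALSE)
  residual <- 100 * measured / reference
  data.frame(residual_pct = residual,
             stable = residual >= window[1L] & residual <= window[2L])
}

#' Assess a storage-stability series
#'
#' Computes, for each condition x day x analyte, the mean across subjects of
#' the per-subject residual (measured over the subject's own day-0 fresh
#' reference) and classifies it against the acceptance window.
#'
#' @param series `data.frame` with columns `subject`, `condition`, `day`,
#'   `analyte`, `measured_conc` (day-0 rows required per subject/condition)
#' @param window acceptance window, default `c(85, 115)`
#' @return `data.frame`: `analyte`, `condition`, `day`, `residual_pct`
#'   (mean across subjects), `stable`
#' @export
stabilityAssessSeries <- function(series, window = c(85, 115)) {
  need <- c("subject", "condition", "day", "analyte", "measured_conc")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("stability series missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!any(series$day == 0))
    stop("no day-0 reference rows in the series", call. = FALSE)
  out <- list()
  for (an in unique(series$analyte)) {
    for (cond in unique(series$condition)) {
      d <- series[series$analyte == an & series$condition == cond, ]
      ref <- d[d$day == 0, ]
      refBySubj <- tapply(ref$measured_conc, ref$subject, mean)
      for (day in sort(unique(d$day[d$day > 0]))) {
        dd <- d[d$day == day, ]
        res <- 100 * dd$measured_conc / as.numeric(refBySubj[dd$subject])
        meanRes <- mean(res)
        out[[length(out) + 1L]] <- data.frame(
          analyte = an, condition = cond, day = day,
          residual_pct = meanRes,
          stable = meanRes >= window[1L] & meanRes <= window[2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Accuracy of stressed QC samples
#'
#' Freeze-thaw and autosampler-stability tests reuse the background-addition
#' accuracy formula on stressed QCB/QCC replicates: the measured mean of the
#' stressed samples against the batch endogenous mean plus spike.
#'
#' @param stressed measured concentrations of the stressed replicates (ng/ml)
#' @param endogenousMean batch endogenous mean (ng/ml)
#' @param spike spiked amount (ng/ml, > 0)
#' @return accuracy in percent
#' @examples
#' freezeThawAutosamplerAccuracy(c(64.8, 65.3, 65.0), 40.1, 25)
#' @export
freezeThawAutosamplerAccuracy <- function(stressed, endogenousMean, spike) {
  if (length(stressed) < 1L) stop("no stressed measurements", call. = FALSE)
  accuracyBackgroundAddition(mean(stressed), endogenousMean, spike)
}

#' Batch-to-batch accuracy and precision at one QC level
#'
#' Pools per-replicate accuracies — each replicate referred to its own
#' batch's endogenous mean — across all batches carrying the level, and
#' reports the pooled mean accuracy and the CV of the pooled measured
#' concentrations. Simple averaging of per-batch summary rows does not in
#' general reproduce pooled statistics, so pooling at replicate level is
#' the package's documented aggregation rule.
#'
#' @param concTable QC concentration table (see [summarizeValidation()])
#' @param level the `level_label` to aggregate (a spiked level)
#' @return list with `accuracy_pct`, `cv_pct`, `n`
#' @export
batchToBatchStats <- function(concTable, level) {
  need <- c("batch", "level_label", "spike_ng_ml", "analyte", "conc_ng_ml")
  miss <- setdiff(need, names(concTable))
  if (length(miss))
    stop("QC concentration table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(concTable$analyte)) != 1L)
    stop("supply one analyte at a time", call. = FALSE)
  batches <- sort(unique(concTable$batch))
  if (length(batches) < 2L) stop("need >= 2 batches", call. = FALSE)
  pooledAcc <- numeric(0); pooledConc <- numeric(0)
  for (b in batches) {
    d <- concTable[concTable$batch == b, ]
    v <- d$conc_ng_ml[d$level_label == level]
    if (!length(v)) {
      warning("level ", level, " missing in batch ", b,
              "; computed on available batches", call. = FALSE)
      next
    }
    spike <- unique(d$spike_ng_ml[d$level_label == level])[1L]
    e <- estimateEndogenous(d$conc_ng_ml[d$spike_ng_ml == 0])
    if (spike > 0) pooledAcc <- c(pooledAcc, 100 * v / (e + spike))
    pooledConc <- c(pooledConc, v)
  }
  list(accuracy_pct = if (length(pooledAcc)) mean(pooledAcc) else NA_real_,
       cv_pct = precisionCV(pooledConc),
       n = length(pooledConc))
}

#' Build the validation ledger from back-calculated QC concentrations
#'
#' Computes the full within-batch and batch-to-batch accuracy/precision
#' ledger of a background-addition validation study. Within each batch, the
#' blank-QC mean is that batch's endogenous estimate, and each spiked
#' level's accuracy is `100 * mean / (endogenous + spike)`. Batch-to-batch
#' statistics pool per-replicate accuracies (each replicate referred to its
#' own batch's endogenous mean) across all batches; precision is the CV of
#' the pooled measured concentrations.
#'
#' @param concTable `data.frame` with columns `batch`, `level_label`,
#'   `spike_ng_ml`, `replicate`, `analyte`, `conc_ng_ml` (e.g. from
#'   [backCalculateBatches()] on [generateValidationBatches()] output)
#' @param recovery,matrixEffect optional `data.frame`s from
#'   [assessRecoveryMatrix()]
#' @param stability optional `data.frame` from [stabilityAssessSeries()]
#' @return a [ValidationReport-class]
#' @export
summarizeValidation <- function(concTable, recovery = NULL,
                                matrixEffect = NULL, stability = NULL) {
  need <- c("batch", "level_label", "spike_ng_ml", "replicate", "analyte",
            "conc_ng_ml")
  miss <- setdiff(need, names(concTable))
  if (length(miss))
    stop("QC concentration table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  wb <- list(); b2b <- list(); endo <- list()
  for (an in unique(concTable$analyte)) {
    d <- concTable[concTable$analyte == an, ]
    batches <- sort(unique(d$batch))
    endoByBatch <- numeric(0)
    for (b in batches) {
      blanks <- d$conc_ng_ml[d$batch == b & d$spike_ng_ml == 0]
      if (length(blanks) < 2L)
        stop("batch ", b, " has < 2 blank replicates for ", an, call. = FALSE)
      endoByBatch[as.character(b)] <- estimateEndogenous(blanks)
      endo[[length(endo) + 1L]] <- data.frame(
        analyte = an, batch = b,
        endogenous_ng_ml = endoByBatch[as.character(b)],
        stringsAsFactors = FALSE)
    }
    levels <- unique(d[, c("level_label", "spike_ng_ml")])
    for (li in seq_len(nrow(levels))) {
      lev <- levels$level_label[li]; spike <- levels$spike_ng_ml[li]
      pooledConc <- numeric(0); pooledAcc <- numeric(0); nb <- 0L
      for (b in batches) {
        v <- d$conc_ng_ml[d$batch == b & d$level_label == lev]
        if (!length(v)) {
          warning("level ", lev, " missing in batch ", b, " for ", an,
                  call. = FALSE)
          next
        }
        nb <- nb + 1L
        e <- endoByBatch[as.character(b)]
        acc <- if (spike > 0)
          accuracyBackgroundAddition(mean(v), e, spike) else NA_real_
        wb[[length(wb) + 1L]] <- data.frame(
          analyte = an, batch = b, level_label = lev,
          nominal_ng_ml = if (spike > 0) e + spike else e,
          mean_ng_ml = mean(v), accuracy_pct = acc,
          cv_pct = precisionCV(v), n = length(v),
          stringsAsFactors = FALSE)
        pooledConc <- c(pooledConc, v)
        if (spike > 0)
          pooledAcc <- c(pooledAcc, 100 * v / (e + spike))
      }
      if (nb >= 2L) {
        b2b[[length(b2b) + 1L]] <- data.frame(
          analyte = an, level_label = lev,
          accuracy_pct = if (length(pooledAcc)) mean(pooledAcc) else NA_real_,
          cv_pct = precisionCV(pooledConc),
          n = length(pooledConc), stringsAsFactors = FALSE)
      }
    }
  }
  emptyDF <- function(x) if (is.null(x) || !nrow(x)) data.frame() else x
  new("ValidationReport",
      withinBatch = do.call(rbind, wb),
      batchToBatch = if (length(b2b)) do.call(rbind, b2b) else data.frame(),
      endogenous = do.call(rbind, endo),
      recovery = emptyDF(recovery),
      matrixEffect = emptyDF(matrixEffect),
      stability = emptyDF(stability))
}
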
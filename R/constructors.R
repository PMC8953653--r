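#' @include AllClasses.R AllGenerics.R
NULL

#' Default calibration ladder (ng/ml)
#'
#' The eight-point surrogate-matrix calibration ladder covering the validated
#' range 0.5–500 ng/ml for both stereoisomers.
#'
#' @return numeric vector `c(0.5, 1, 2, 5, 20, 50, 200, 500)`
#' @export
defaultCalibrationLevels <- function() c(0.5, 1, 2, 5, 20, 50, 200, 500)

#' Default QC spike levels (ng/ml added on top of endogenous)
#'
#' LLOQ, low (QCA), medium (QCB) and high (QCC) background-addition spikes.
#' The leading 0 is the blank (endogenous-only) QC.
#'
#' @param includeBlank prepend the 0 ng/ml blank level (default `TRUE`)
#' @return named numeric vector of spikes
#' @export
defaultQCSpikes <- function(includeBlank = TRUE) {
  s <- c(endogenous = 0, LLOQ = 0.5, QCA = 1.5, QCB = 25, QCC = 400)
  if (includeBlank) s else s[-1L]
}

#' Construct the assay ground truth for simulation
#'
#' Defaults reproduce the validated assay's observed behaviour: an
#' IS-normalised response of 0.01 ratio units per ng/ml, area-ratio CVs of a
#' few percent (within the 1–10% range seen across QC levels), endogenous
#' plasma levels of ~39 ng/ml 4beta-OHC and ~6.9 ng/ml 4alpha-OHC (the
#' across-batch means of the validation study), and six plasma lots with
#' extraction-recovery factors centred just below 1 and mild ionisation
#' enhancement.
#'
#' @param slopeRatio response factor, area ratio per ng/ml
#' @param intercept area-ratio intercept
#' @param cvProportional proportional CV of the analyte/IS area ratio
#' @param sdAdditive additive noise SD in area-ratio units
#' @param endogenous4b,endogenous4a endogenous plasma levels (ng/ml)
#' @param matrixFactorPerLot named numeric, lot -> matrix factor
#' @param recoveryFactorPerLot named numeric, lot -> recovery factor
#' @param isNominalArea nominal internal-standard area (counts)
#' @param isCorrelation correlation of analyte and IS proportional noise
#' @param betweenBatchCV between-batch CV of the endogenous level
#' @param seed default integer seed for the generators
#' @return an [AssayGroundTruth-class] object
#' @examples
#' truth <- assayGroundTruth()
#' generateCalibrationRun(truth)
#' @export
assayGroundTruth <- function(slopeRatio = 0.01,
                             intercept = 0,
                             cvProportional = 0.04,
                             sdAdditive = 5e-4,
                             endogenous4b = 39.3,
                             endogenous4a = 6.9,
                             matrixFactorPerLot = c(lot1 = 0.97, lot2 = 1.00,
                                                    lot3 = 1.02, lot4 = 1.04,
                                                    lot5 = 1.06, lot6 = 1.09),
                             recoveryFactorPerLot = c(lot1 = 0.93, lot2 = 0.95,
                                                      lot3 = 0.97, lot4 = 0.99,
                                                      lot5 = 1.01, lot6 = 1.03),
                             isNominalArea = 1e5,
                             isCorrelation = 0.8,
                             betweenBatchCV = 0.05,
                             seed = 20220216L) {
  new("AssayGroundTruth",
      slopeRatio = slopeRatio, intercept = intercept,
      cvProportional = cvProportional, sdAdditive = sdAdditive,
      endogenous4b = endogenous4b, endogenous4a = endogenous4a,
      matrixFactorPerLot = matrixFactorPerLot,
      recoveryFactorPerLot = recoveryFactorPerLot,
      isNominalArea = isNominalArea, isCorrelation = isCorrelation,
      betweenBatchCV = betweenBatchCV, seed = as.integer(seed))
}

#' Construct a cohort specification
#'
#' Defaults are the published three-group clinical application: 9 healthy
#' volunteers, 15 stage 3–5 CKD patients and 14 stage 5D (dialysis) CKD
#' patients, with the reported group means and SDs of plasma 4beta-OHC,
#' 4alpha-OHC and total cholesterol.
#'
#' @param n named integer vector of group sizes
#' @param mean4b,sd4b 4beta-OHC mean/SD per group (ng/ml)
#' @param mean4a,sd4a 4alpha-OHC mean/SD per group (ng/ml)
#' @param meanTC,sdTC total cholesterol mean/SD per group (mg/dl)
#' @param family `"normal"` (truncated at 0) or `"lognormal"`
#' @param correlation common within-subject correlation of the three
#'   measures (default 0)
#' @param seed default integer seed
#' @return a [CohortSpec-class]
#' @examples
#' spec <- cohortSpec()
#' nrow(generateCohort(spec))  # 38 subjects
#' @export
cohortSpec <- function(n = c(healthy = 9L, CKD3_5 = 15L, CKD5D = 14L),
                       mean4b = c(23.6, 31.2, 22.7),
                       sd4b = c(7.4, 10.3, 6.7),
                       mean4a = c(3.6, 5.9, 4.8),
                       sd4a = c(0.9, 1.4, 0.9),
                       meanTC = c(159.4, 195.6, 160.0),
                       sdTC = c(38.9, 23.4, 39.6),
                       family = c("normal", "lognormal"),
                       correlation = 0,
                       seed = 20220216L) {
  family <- match.arg(family)
  n <- stats::setNames(as.integer(n), names(n))
  new("CohortSpec", n = n, mean4b = mean4b, sd4b = sd4b,
      mean4a = mean4a, sd4a = sd4a, meanTC = meanTC, sdTC = sdTC,
      family = family, correlation = correlation, seed = as.integer(seed))
}

#' Construct a peak model
#'
#' @param retentionTime apex position (min)
#' @param height apex intensity (counts)
#' @param sigma Gaussian width (min)
#' @param tailing exponential tailing constant (min); 0 for a pure Gaussian
#' @param transitionLabel MRM transition label
#' @return a [PeakModel-class]
#' @examples
#' peakModel(8.3, height = 5e4)           # 4beta-OHC
#' peakModel(8.8, height = 5e3)           # 4alpha-OHC, same transition
#' @export
peakModel <- function(retentionTime, height = 1e4, sigma = 0.02, tailing = 0,
                      transitionLabel = .TRANSITION_ANALYTE) {
  new("PeakModel", retentionTime = retentionTime, height = height,
      sigma = sigma, tailing = tailing, transitionLabel = transitionLabel)
}

#' Construct a gradient program
#'
#' The default is the validated separation's binary gradient: hold at 80% B
#' for 0.5 min, ramp linearly to 95% B at 6.0 min, hold 4 min, return to
#' 80% B and re-equilibrate to 12.5 min, at 0.4 ml/min.
#'
#' @param breakpoints two-column matrix or data.frame `(time_min, percent_B)`
#' @param flow flow rate (ml/min)
#' @param totalRuntime run length (min)
#' @return a [GradientProgram-class]
#' @examples
#' gp <- gradientProgram()
#' gradientComposition(gp, 7)   # 95 (inside the hold)
#' @export
gradientProgram <- function(breakpoints = cbind(time_min = c(0, 0.5, 6, 10, 10.1, 12.5),
                                                percent_B = c(80, 80, 95, 95, 80, 80)),
                            flow = 0.4, totalRuntime = 12.5) {
  bp <- as.matrix(breakpoints)
  colnames(bp) <- c("time_min", "percent_B")
  new("GradientProgram", breakpoints = bp, flow = flow,
      totalRuntime = totalRuntime)
}

## ---- accessors ----

#' @rdname rtime
#' @export
setMethod("rtime", "ChromatogramTrace", function(object) object@times)

#' @rdname intensity
#' @export
setMethod("intensity", "ChromatogramTrace", function(object) object@intensities)

#' @rdname transitionLabel
#' @export
setMethod("transitionLabel", "ChromatogramTrace",
          function(object) object@transitionLabel)

#' @rdname transitionLabel
#' @export
setMethod("transitionLabel", "PeakModel", function(object) object@transitionLabel)

#' Calibration coefficients
#'
#' @param object a [CalibrationModel-class]
#' @param ... ignored
#' @return named numeric `c(intercept, slope)`
#' @export
setMethod("coef", "CalibrationModel", function(object, ...) {
  c(intercept = object@intercept, slope = object@slope)
})

#' @rdname rSquared
#' @export
setMethod("rSquared", "CalibrationModel", function(object, weighted = TRUE) {
  if (weighted) object@rSquaredWeighted else object@rSquaredUnweighted
})

#' @rdname weightingScheme
#' @export
setMethod("weightingScheme", "CalibrationModel", function(object) object@weighting)

#' @rdname levelTable
#' @export
setMethod("levelTable", "CalibrationModel", function(object) object@levelTable)

## ---- show methods ----

setMethod("show", "AssayGroundTruth", function(object) {
  cat("AssayGroundTruth\n")
  cat(sprintf("  response: ratio = %.4g + %.4g * conc [ng/ml]\n",
              object@intercept, object@slopeRatio))
  cat(sprintf("  noise: prop CV %.1f%%, additive SD %.2g (ratio units)\n",
              100 * object@cvProportional, object@sdAdditive))
  cat(sprintf("  endogenous: 4b %.1f ng/ml, 4a %.1f ng/ml (between-batch CV %.0f%%)\n",
              object@endogenous4b, object@endogenous4a,
              100 * object@betweenBatchCV))
  cat(sprintf("  lots: %d (recovery %.2f-%.2f, matrix %.2f-%.2f)\n",
              length(object@recoveryFactorPerLot),
              min(object@recoveryFactorPerLot), max(object@recoveryFactorPerLot),
              min(object@matrixFactorPerLot), max(object@matrixFactorPerLot)))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec (", object@family, " family)\n", sep = "")
  df <- data.frame(group = names(object@n), n = object@n,
                   mean_4b = object@mean4b, sd_4b = object@sd4b,
                   mean_4a = object@mean4a, sd_4a = object@sd4a,
                   mean_TC = object@meanTC, sd_TC = object@sdTC,
                   row.names = NULL)
  print(df, row.names = FALSE)
})

setMethod("show", "ChromatogramTrace", function(object) {
  n <- length(object@times)
  cat("ChromatogramTrace [", object@transitionLabel, "]\n", sep = "")
  if (n) {
    cat(sprintf("  %d points, %.2f-%.2f min (step %.4g min)\n",
                n, object@times[1L], object@times[n],
                if (n > 1L) object@times[2L] - object@times[1L] else NA_real_))
    cat(sprintf("  max intensity %.4g at %.2f min\n",
                max(object@intensities),
                object@times[which.max(object@intensities)]))
  }
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel (weighting ", object@weighting, ")\n", sep = "")
  cat(sprintf("  ratio = %.6g + %.6g * conc;  n = %d\n",
              object@intercept, object@slope, object@n))
  cat(sprintf("  r2 (weighted) = %.5f, r2 (unweighted) = %.5f\n",
              object@rSquaredWeighted, object@rSquaredUnweighted))
  if (nrow(object@levelTable)) {
    cat("  calibrators:\n")
    print(object@levelTable, row.names = FALSE, digits = 4)
  }
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n")
  if (nrow(object@withinBatch)) {
    cat(" within-batch:\n")
    print(object@withinBatch, row.names = FALSE, digits = 4)
  }
  if (nrow(object@batchToBatch)) {
    cat(" batch-to-batch:\n")
    print(object@batchToBatch, row.names = FALSE, digits = 4)
  }
  if (nrow(object@recovery)) {
    cat(" apparent recovery [%raw, per level]:\n")
    print(unique(object@recovery[, intersect(c("analyte", "level_label",
                                               "mean_pct", "min_pct", "max_pct"),
                                             names(object@recovery))]),
          row.names = FALSE, digits = 4)
  }
  if (nrow(object@matrixEffect)) {
    cat(" matrix effect [%, per level]:\n")
    print(unique(object@matrixEffect[, intersect(c("analyte", "level_label",
                                                   "mean_pct", "min_pct", "max_pct"),
                                                 names(object@matrixEffect))]),
          row.names = FALSE, digits = 4)
  }
  if (nrow(object@stability)) {
    cat(" stability rows:", nrow(object@stability), "\n")
  }
})

setMethod("show", "GroupComparison", function(object) {
  cat(object@testName, ": statistic = ", format(object@statistic, digits = 5),
      ", p = ", format.pval(object@pValue, digits = 4), "\n", sep = "")
  if (nrow(object@posthoc)) {
    cat("  post hoc (", object@method, "):\n", sep = "")
    print(object@posthoc, row.names = FALSE, digits = 4)
  }
})
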
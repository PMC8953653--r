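#' @import methods
NULL

## Analyte keys used throughout the package. Both stereoisomers share one MRM
## transition (they differ only in retention time); the deuterated internal
## standard has its own.
.ANALYTES <- c("4b_OHC", "4a_OHC")
.TRANSITION_ANALYTE <- "613.3>490.5"
.TRANSITION_IS <- "620.3>497.6"
.LEVEL_LABELS <- c("endogenous", "LLOQ", "QCA", "QCB", "QCC")
.DESIGN_ARMS <- c("pre_extraction_spike", "post_extraction_spike", "neat_solution")
.STAB_CONDITIONS <- c("open_RT", "open_4C", "closed_RT", "closed_4C")
.COHORT_GROUPS <- c("healthy", "CKD3_5", "CKD5D")

#' Ground truth of the simulated assay
#'
#' Holds the unobservable quantities behind a stable-isotope-dilution
#' LC-MS/MS oxysterol assay: the IS-normalised response factor, endogenous
#' plasma levels of both stereoisomers, per-lot extraction-recovery and
#' matrix-effect factors, and the noise law. Every synthetic-data generator
#' takes one of these, so a whole validation study can be generated with
#' known truth and the downstream estimators checked against it.
#'
#' The noise model is multiplicative + additive Gaussian:
#' `area = expected * (1 + eps_prop) + eps_add`. Analyte and internal-standard
#' proportional errors are drawn jointly with correlation `isCorrelation`
#' (isotope dilution cancels most preparation variability); the per-area
#' proportional SD is scaled so that the analyte/IS *ratio* CV equals
#' `cvProportional` to first order.
#'
#' @slot slopeRatio response factor: area ratio per ng/ml (> 0)
#' @slot intercept area-ratio intercept of the response line
#' @slot cvProportional proportional CV of the area ratio (fraction, >= 0)
#' @slot sdAdditive additive noise SD in area-ratio units (>= 0)
#' @slot endogenous4b,endogenous4a endogenous plasma levels (ng/ml)
#' @slot matrixFactorPerLot named numeric, lot -> ionisation matrix factor
#'   (1 = no suppression/enhancement)
#' @slot recoveryFactorPerLot named numeric, lot -> extraction recovery factor
#' @slot isNominalArea nominal internal-standard peak area (counts)
#' @slot isCorrelation correlation of analyte and IS proportional errors,
#'   in `[0, 1)`
#' @slot betweenBatchCV CV of the per-batch endogenous level around the
#'   global endogenous level (fraction)
#' @slot seed default integer seed used by the generators
#' @seealso [assayGroundTruth()] for the user constructor with defaults
#'   matching the validated assay's observed behaviour.
#' @export
setClass("AssayGroundTruth",
  representation(
    slopeRatio = "numeric",
    intercept = "numeric",
    cvProportional = "numeric",
    sdAdditive = "numeric",
    endogenous4b = "numeric",
    endogenous4a = "numeric",
    matrixFactorPerLot = "numeric",
    recoveryFactorPerLot = "numeric",
    isNominalArea = "numeric",
    isCorrelation = "numeric",
    betweenBatchCV = "numeric",
    seed = "integer"
  )
)

setValidity("AssayGroundTruth", function(object) {
  msg <- character()
  if (length(object@slopeRatio) != 1L || object@slopeRatio <= 0)
    msg <- c(msg, "slopeRatio must be a single positive number")
  if (object@cvProportional < 0) msg <- c(msg, "cvProportional must be >= 0")
  if (object@sdAdditive < 0) msg <- c(msg, "sdAdditive must be >= 0")
  if (object@endogenous4b < 0 || object@endogenous4a < 0)
    msg <- c(msg, "endogenous levels must be >= 0")
  if (any(object@matrixFactorPerLot <= 0))
    msg <- c(msg, "all matrix factors must be > 0")
  if (any(object@recoveryFactorPerLot <= 0))
    msg <- c(msg, "all recovery factors must be > 0")
  if (length(object@matrixFactorPerLot) != length(object@recoveryFactorPerLot))
    msg <- c(msg, "matrix and recovery factor maps must cover the same lots")
  if (object@isNominalArea <= 0) msg <- c(msg, "isNominalArea must be > 0")
  if (object@isCorrelation < 0 || object@isCorrelation >= 1)
    msg <- c(msg, "isCorrelation must be in [0, 1)")
  if (object@betweenBatchCV < 0) msg <- c(msg, "betweenBatchCV must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of a simulated three-group cohort
#'
#' Group sizes and the per-group mean and SD of plasma 4beta-OHC, 4alpha-OHC
#' and total cholesterol for a healthy / CKD stage 3-5 / CKD stage 5D cohort.
#' Defaults are the published clinical-application values (n = 9/15/14).
#'
#' @slot n named integer vector of group sizes (healthy, CKD3_5, CKD5D)
#' @slot mean4b,sd4b per-group mean/SD of 4beta-OHC (ng/ml)
#' @slot mean4a,sd4a per-group mean/SD of 4alpha-OHC (ng/ml)
#' @slot meanTC,sdTC per-group mean/SD of total cholesterol (mg/dl)
#' @slot family `"normal"` (truncated at 0) or `"lognormal"` (moment-matched)
#' @slot correlation common pairwise correlation of the three measures
#'   within a subject (default 0)
#' @slot seed default integer seed
#' @seealso [cohortSpec()]
#' @export
setClass("CohortSpec",
  representation(
    n = "integer",
    mean4b = "numeric", sd4b = "numeric",
    mean4a = "numeric", sd4a = "numeric",
    meanTC = "numeric", sdTC = "numeric",
    family = "character",
    correlation = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  k <- length(object@n)
  if (k < 2L) msg <- c(msg, "at least two groups are required")
  if (any(object@n < 2L)) msg <- c(msg, "each group needs n >= 2")
  if (is.null(names(object@n)) || any(!nzchar(names(object@n))))
    msg <- c(msg, "group sizes must be named")
  for (s in c("mean4b", "sd4b", "mean4a", "sd4a", "meanTC", "sdTC"))
    if (length(slot(object, s)) != k)
      msg <- c(msg, sprintf("%s must have one value per group", s))
  if (any(c(object@sd4b, object@sd4a, object@sdTC) < 0))
    msg <- c(msg, "SDs must be >= 0")
  if (!object@family %in% c("normal", "lognormal"))
    msg <- c(msg, "family must be 'normal' or 'lognormal'")
  if (object@family == "lognormal" &&
      any(c(object@mean4b, object@mean4a, object@meanTC) <= 0))
    msg <- c(msg, "lognormal family requires strictly positive means")
  if (object@correlation < -1 || object@correlation > 1)
    msg <- c(msg, "correlation must be in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' A single chromatographic peak
#'
#' Exponentially modified Gaussian peak model; `tailing = 0` gives a pure
#' Gaussian with apex `height` at `retentionTime`.
#'
#' @slot retentionTime apex position (min, >= 0)
#' @slot height apex intensity for the pure Gaussian (counts, >= 0)
#' @slot sigma Gaussian width (min, > 0)
#' @slot tailing exponential tailing time constant (min, >= 0; 0 = none)
#' @slot transitionLabel MRM transition the peak belongs to
#' @seealso [peakModel()]
#' @export
setClass("PeakModel",
  representation(
    retentionTime = "numeric",
    height = "numeric",
    sigma = "numeric",
    tailing = "numeric",
    transitionLabel = "character"
  )
)

setValidity("PeakModel", function(object) {
  msg <- character()
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@height < 0) msg <- c(msg, "height must be >= 0")
  if (object@retentionTime < 0) msg <- c(msg, "retentionTime must be >= 0")
  if (object@tailing < 0) msg <- c(msg, "tailing must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Time-ordered intensity series for one MRM transition
#'
#' @slot times uniform, strictly increasing retention-time grid (min)
#' @slot intensities non-negative intensities (counts), same length
#' @slot transitionLabel MRM transition, e.g. `"613.3>490.5"`
#' @seealso [simulateTrace()], [integratePeak()]
#' @export
setClass("ChromatogramTrace",
  representation(
    times = "numeric",
    intensities = "numeric",
    transitionLabel = "character"
  )
)

setValidity("ChromatogramTrace", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n != length(object@intensities))
    msg <- c(msg, "times and intensities must have equal length")
  if (n >= 2L) {
    d <- diff(object@times)
    if (any(d <= 0)) msg <- c(msg, "times must be strictly increasing")
    else if (diff(range(d)) > 1e-8 * mean(d))
      msg <- c(msg, "times must be a uniform grid")
  }
  if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be >= 0 (baseline-clamped)")
  if (length(msg)) msg else TRUE
})

#' Piecewise-linear binary gradient program
#'
#' @slot breakpoints two-column matrix `(time_min, percent_B)` with
#'   non-decreasing times and `%B` in `[0, 100]`
#' @slot flow flow rate (ml/min)
#' @slot totalRuntime run length (min)
#' @seealso [gradientProgram()], [gradientComposition()]
#' @export
setClass("GradientProgram",
  representation(breakpoints = "matrix", flow = "numeric", totalRuntime = "numeric")
)

setValidity("GradientProgram", function(object) {
  bp <- object@breakpoints
  msg <- character()
  if (ncol(bp) != 2L) msg <- c(msg, "breakpoints must have two columns (time, %B)")
  else {
    if (is.unsorted(bp[, 1L])) msg <- c(msg, "breakpoint times must be non-decreasing")
    if (any(bp[, 2L] < 0 | bp[, 2L] > 100)) msg <- c(msg, "%B must be in [0, 100]")
    if (bp[nrow(bp), 1L] > object@totalRuntime)
      msg <- c(msg, "last breakpoint exceeds totalRuntime")
  }
  if (object@flow <= 0) msg <- c(msg, "flow must be > 0")
  if (length(msg)) msg else TRUE
})

#' Weighted linear calibration model
#'
#' Result of a (weighted) least-squares fit of analyte/IS area ratio against
#' nominal concentration in surrogate matrix. Carries both the weighted and
#' the unweighted coefficient of determination.
#'
#' @slot slope area ratio per ng/ml
#' @slot intercept area ratio
#' @slot rSquaredWeighted r-squared of the weighted fit (about the weighted mean)
#' @slot rSquaredUnweighted ordinary r-squared of the same coefficients
#' @slot weighting weighting tag: `"1/x"`, `"1/x^2"` or `"none"`
#' @slot levelTable per-calibrator back-calculation table
#'   (`level_ng_ml`, `area_ratio`, `back_calc_ng_ml`, `accuracy_pct`)
#' @slot n number of calibrators used
#' @seealso [fitCalibration()], [backCalculate()], [assessCalibrators()]
#' @export
setClass("CalibrationModel",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquaredWeighted = "numeric",
    rSquaredUnweighted = "numeric",
    weighting = "character",
    levelTable = "data.frame",
    n = "integer"
  )
)

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (!object@weighting %in% c("1/x", "1/x^2", "none"))
    msg <- c(msg, "weighting must be one of '1/x', '1/x^2', 'none'")
  ok <- function(r) is.na(r) || (r >= -1e-8 && r <= 1 + 1e-8)
  if (!ok(object@rSquaredWeighted) || !ok(object@rSquaredUnweighted))
    msg <- c(msg, "r-squared values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Full bioanalytical validation ledger
#'
#' Mirrors the row structure of a per-analyte validation summary table:
#' per-batch (within-batch) endogenous mean, background-addition accuracy
#' and precision at each QC level, pooled batch-to-batch statistics, and —
#' when the corresponding experiments are supplied — apparent recovery,
#' matrix effect and stability blocks.
#'
#' @slot withinBatch data.frame: analyte, batch, level_label, nominal
#'   (ng/ml), mean (ng/ml), accuracy_pct, cv_pct, n
#' @slot batchToBatch data.frame: analyte, level_label, accuracy_pct,
#'   cv_pct, n
#' @slot endogenous data.frame: analyte, batch, mean endogenous (ng/ml)
#' @slot recovery data.frame: analyte, level_label, lot, recovery_pct plus
#'   per-level mean/min/max (see [assessRecoveryMatrix()])
#' @slot matrixEffect data.frame, same layout for matrix effect
#' @slot stability data.frame of [stabilityAssess()] results
#' @export
setClass("ValidationReport",
  representation(
    withinBatch = "data.frame",
    batchToBatch = "data.frame",
    endogenous = "data.frame",
    recovery = "data.frame",
    matrixEffect = "data.frame",
    stability = "data.frame"
  )
)

setValidity("ValidationReport", function(object) {
  msg <- character()
  wb <- object@withinBatch
  if (nrow(wb) && any(wb$cv_pct < 0, na.rm = TRUE))
    msg <- c(msg, "CVs must be non-negative")
  if (nrow(wb) && any(wb$accuracy_pct <= 0, na.rm = TRUE))
    msg <- c(msg, "accuracies must be positive")
  rec <- object@recovery
  if (nrow(rec) && all(c("mean_pct", "min_pct", "max_pct") %in% names(rec))) {
    if (any(rec$mean_pct < rec$min_pct - 1e-9 | rec$mean_pct > rec$max_pct + 1e-9))
      msg <- c(msg, "recovery ranges must bracket their means")
  }
  if (length(msg)) msg else TRUE
})

#' Result of one between-group hypothesis test
#'
#' @slot testName e.g. `"one-way ANOVA"` or `"Kruskal-Wallis"`
#' @slot statistic the F or H statistic
#' @slot parameter degrees of freedom (named)
#' @slot pValue omnibus p-value
#' @slot posthoc data.frame of pairwise results: comparison, estimate,
#'   statistic, p_raw, p_adjusted, significant
#' @slot method short description of the post-hoc procedure
#' @export
setClass("GroupComparison",
  representation(
    testName = "character",
    statistic = "numeric",
    parameter = "numeric",
    pValue = "numeric",
    posthoc = "data.frame",
    method = "character"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in [0, 1]")
  ph <- object@posthoc
  if (nrow(ph) && all(c("p_raw", "p_adjusted") %in% names(ph))) {
    if (any(ph$p_adjusted < ph$p_raw - 1e-9, na.rm = TRUE))
      msg <- c(msg, "adjusted p-values must be >= raw p-values")
  }
  if (length(msg)) msg else TRUE
})
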
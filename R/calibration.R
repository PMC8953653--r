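#' @include AllClasses.R AllGenerics.R utils.R
NULL

.calWeights <- function(levels, weighting) {
  switch(weighting,
         "none" = rep(1, length(levels)),
         "1/x" = 1 / levels,
         "1/x^2" = 1 / levels^2,
         stop("unknown weighting scheme: ", weighting, call. = FALSE))
}

#' Fit a weighted linear calibration
#'
#' Weighted least-squares fit of analyte/IS area ratio against nominal
#' concentration, minimising `sum(w_i * (y_i - a - b x_i)^2)` with
#' `w_i = 1/x_i` by default — the standard bioanalytical weighting that
#' equalises the relative influence of low and high calibrators. The
#' weighted r-squared is `1 - SSE_w / SST_w` with the weighted total sum of
#' squares about the weighted mean; the ordinary (unweighted) r-squared of
#' the same line is carried alongside, since instrument software does not
#' always report which convention it prints.
#'
#' @param levels nominal calibrator concentrations (ng/ml); >= 2 distinct
#'   values, strictly positive for the `1/x` family
#' @param areaRatios observed analyte/IS area ratios, same length
#' @param weighting `"1/x"` (default), `"1/x^2"` or `"none"`
#' @return a [CalibrationModel-class]
#' @examples
#' x <- defaultCalibrationLevels()
#' fit <- fitCalibration(x, 0.01 * x)
#' coef(fit)                       # intercept 0, slope 0.01
#' rSquared(fit)                   # 1
#' @export
fitCalibration <- function(levels, areaRatios, weighting = c("1/x", "none", "1/x^2")) {
  weighting <- match.arg(weighting)
  if (length(levels) != length(areaRatios))
    stop("levels and areaRatios must have equal length", call. = FALSE)
  if (length(unique(levels)) < 2L)
    stop("singular design: need >= 2 distinct calibrator levels", call. = FALSE)
  if (weighting != "none" && any(levels <= 0))
    stop("nonpositive level with ", weighting, " weighting", call. = FALSE)
  w <- .calWeights(levels, weighting)
  fit <- stats::lm(areaRatios ~ levels, weights = w)
  a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  resid <- areaRatios - (a + b * levels)
  ybarW <- sum(w * areaRatios) / sum(w)
  sseW <- sum(w * resid^2)
  sstW <- sum(w * (areaRatios - ybarW)^2)
  r2w <- if (sstW > 0) 1 - sseW / sstW else NA_real_
  sse <- sum(resid^2)
  sst <- sum((areaRatios - mean(areaRatios))^2)
  r2u <- if (sst > 0) 1 - sse / sst else NA_real_
  backCalc <- (areaRatios - a) / b
  lt <- data.frame(level_ng_ml = levels,
                   area_ratio = areaRatios,
                   back_calc_ng_ml = backCalc,
                   accuracy_pct = 100 * backCalc / levels)
  new("CalibrationModel", slope = b, intercept = a,
      rSquaredWeighted = min(max(r2w, 0), 1),
      rSquaredUnweighted = min(max(r2u, 0), 1),
      weighting = weighting, levelTable = lt, n = length(levels))
}

#' @rdname backCalculate
#' @export
setMethod("backCalculate", "CalibrationModel", function(model, areaRatio) {
  if (model@slope == 0) stop("zero calibration slope", call. = FALSE)
  (areaRatio - model@intercept) / model@slope
})

#' Assess calibrators against acceptance bands
#'
#' Back-calculates each calibrator through the fitted line and flags it
#' against the regulatory acceptance band: accuracy within 100 +/- 15%
#' (100 +/- 20% at the LLOQ).
#'
#' @param model a [CalibrationModel-class]
#' @param levels nominal concentrations (ng/ml)
#' @param areaRatios observed ratios
#' @param lloq the lower limit of quantification; must be one of `levels`
#' @param band,bandLLOQ half-widths of the acceptance bands (percent points)
#' @return `data.frame` with columns `level_ng_ml`, `area_ratio`,
#'   `back_calc_ng_ml`, `accuracy_pct`, `pass`
#' @examples
#' x <- defaultCalibrationLevels()
#' assessCalibrators(fitCalibration(x, 0.01 * x), x, 0.01 * x)
#' @export
assessCalibrators <- function(model, levels, areaRatios, lloq = 0.5,
                              band = 15, bandLLOQ = 20) {
  stopifnot(is(model, "CalibrationModel"))
  if (!any(abs(levels - lloq) < 1e-12))
    stop("lloq must be one of the calibrator levels", call. = FALSE)
  bc <- backCalculate(model, areaRatios)
  acc <- 100 * bc / levels
  halfWidth <- ifelse(abs(levels - lloq) < 1e-12, bandLLOQ, band)
  data.frame(level_ng_ml = levels,
             area_ratio = areaRatios,
             back_calc_ng_ml = bc,
             accuracy_pct = acc,
             pass = abs(acc - 100) <= halfWidth)
}

#' Nominal concentration added by a volumetric spike
#'
#' Added amount per plasma volume: `solutionConc * spikeVol / plasmaVol`,
#' the assay's convention for background addition (the ~5% volume increment
#' of the 2.5 ul spike into 50 ul plasma is ignored, matching the printed
#' nominal levels).
#'
#' @param solutionConc spiking solution concentration (ng/ml)
#' @param spikeVol spike volume (ul), default 2.5
#' @param plasmaVol plasma volume (ul), default 50
#' @return nominal added concentration (ng/ml)
#' @examples
#' spikeConcentration(8000)    # 400 ng/ml (QCC)
#' spikeConcentration(10000)   # 500 ng/ml (top calibrator)
#' @export
spikeConcentration <- function(solutionConc, spikeVol = 2.5, plasmaVol = 50) {
  if (plasmaVol <= 0) stop("plasma volume must be > 0", call. = FALSE)
  if (spikeVol <= 0) stop("spike volume must be > 0", call. = FALSE)
  if (any(solutionConc < 0)) stop("negative solution concentration", call. = FALSE)
  solutionConc * spikeVol / plasmaVol
}

#' Fit per-analyte calibrations from an area table
#'
#' Convenience wrapper: computes area ratios from a calibration-run table
#' (as produced by [generateCalibrationRun()]) and fits one model per
#' analyte present.
#'
#' @param calTable `data.frame` with columns `level_ng_ml`, `analyte_area`,
#'   `is_area`, `analyte`
#' @param weighting passed to [fitCalibration()]
#' @return named list of [CalibrationModel-class], one per analyte
#' @export
fitCalibrationTable <- function(calTable, weighting = "1/x") {
  need <- c("level_ng_ml", "analyte_area", "is_area", "analyte")
  miss <- setdiff(need, names(calTable))
  if (length(miss))
    stop("calibration table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(calTable, calTable$analyte), function(d) {
    fitCalibration(d$level_ng_ml, d$analyte_area / d$is_area,
                   weighting = weighting)
  })
  out
}

#' Back-calculate a QC area table to concentrations
#'
#' @param areaTable `data.frame` with columns `analyte`, `analyte_area`,
#'   `is_area` (plus any design columns, carried through)
#' @param models named list of [CalibrationModel-class] keyed by analyte
#' @return the table with an added `conc_ng_ml` column
#' @export
backCalculateBatches <- function(areaTable, models) {
  need <- c("analyte", "analyte_area", "is_area")
  miss <- setdiff(need, names(areaTable))
  if (length(miss))
    stop("area table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  missMod <- setdiff(unique(areaTable$analyte), names(models))
  if (length(missMod))
    stop("no calibration model for analyte(s): ",
         paste(missMod, collapse = ", "), call. = FALSE)
  ratio <- areaTable$analyte_area / areaTable$is_area
  conc <- numeric(nrow(areaTable))
  for (an in unique(areaTable$analyte)) {
    i <- areaTable$analyte == an
    conc[i] <- backCalculate(models[[an]], ratio[i])
  }
  areaTable$conc_ng_ml <- conc
  areaTable
}
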
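#' @include AllClasses.R
NULL

#' Retention-time grid of a chromatogram trace
#'
#' @param object a [ChromatogramTrace-class]
#' @return numeric vector of times (min)
#' @export
setGeneric("rtime", function(object) standardGeneric("rtime"))

#' Intensity vector of a chromatogram trace
#'
#' @param object a [ChromatogramTrace-class]
#' @return numeric vector of intensities (counts)
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' MRM transition label
#'
#' @param object a [ChromatogramTrace-class] or [PeakModel-class]
#' @return character scalar, e.g. `"613.3>490.5"`
#' @export
setGeneric("transitionLabel", function(object) standardGeneric("transitionLabel"))

#' Coefficient of determination of a calibration fit
#'
#' @param object a [CalibrationModel-class]
#' @param weighted logical; the weighted (default) or unweighted r-squared.
#'   Both are carried because instrument software does not always say which
#'   one it prints.
#' @return numeric scalar in `[0, 1]`
#' @export
setGeneric("rSquared", function(object, weighted = TRUE) standardGeneric("rSquared"))

#' Weighting scheme recorded with a calibration fit
#'
#' @param object a [CalibrationModel-class]
#' @return character tag (`"1/x"`, `"1/x^2"` or `"none"`)
#' @export
setGeneric("weightingScheme", function(object) standardGeneric("weightingScheme"))

#' Per-level back-calculation table of a calibration fit
#'
#' @param object a [CalibrationModel-class]
#' @return `data.frame` with one row per calibrator
#' @export
setGeneric("levelTable", function(object) standardGeneric("levelTable"))

#' Back-calculate concentration from an analyte/IS area ratio
#'
#' Inverts the linear calibration: `(ratio - intercept) / slope`. Values can
#' be negative on noisy ratios near zero; they are returned as-is so the
#' caller decides about clamping or flagging.
#'
#' @param model a [CalibrationModel-class]
#' @param areaRatio numeric vector of analyte/IS peak-area ratios
#' @return numeric vector of concentrations (ng/ml)
#' @export
setGeneric("backCalculate", function(model, areaRatio) standardGeneric("backCalculate"))
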
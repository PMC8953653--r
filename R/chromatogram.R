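#' @include AllClasses.R constructors.R utils.R
NULL

#' Mobile-phase composition at a time point
#'
#' Linear interpolation of the gradient program's `%B` between breakpoints;
#' constant on holds, continuous everywhere.
#'
#' @param program a [GradientProgram-class]
#' @param t time (min), within `[0, totalRuntime]`
#' @return `%B` at `t` (vectorised over `t`)
#' @examples
#' gp <- gradientProgram()
#' gradientComposition(gp, c(0.25, 3.25, 7))  # 80, 87.5, 95
#' @export
gradientComposition <- function(program, t) {
  stopifnot(is(program, "GradientProgram"))
  validObject(program)
  if (any(t < 0 | t > program@totalRuntime))
    stop("t outside the gradient runtime [0, ",
         program@totalRuntime, "] min", call. = FALSE)
  bp <- program@breakpoints
  stats::approx(bp[, 1L], bp[, 2L], xout = t, rule = 2, ties = "ordered")$y
}

## Peak shape on a time grid. Pure Gaussian for tailing = 0, otherwise an
## exponentially modified Gaussian with the same area h * sigma * sqrt(2*pi).
.peakShape <- function(peak, times) {
  h <- peak@height; rt <- peak@retentionTime; s <- peak@sigma; tau <- peak@tailing
  if (tau <= 0) {
    h * exp(-(times - rt)^2 / (2 * s^2))
  } else {
    ## EMG written via erfcx for numerical stability at small tau
    z <- (s / tau - (times - rt) / s) / sqrt(2)
    erfcx <- function(x) exp(x^2) * (2 * stats::pnorm(-x * sqrt(2)))
    h * s / tau * sqrt(pi / 2) *
      exp(-(times - rt)^2 / (2 * s^2)) * erfcx(z)
  }
}

#' Simulate an MRM chromatogram trace
#'
#' Sums the contributions of a peak panel on a uniform time grid and adds
#' Gaussian baseline noise, clamping at zero. An empty peak list yields a
#' baseline-only trace.
#'
#' @param peaks a list of [PeakModel-class] objects (or a single one)
#' @param from,to time range (min)
#' @param gridStep sampling interval (min, > 0)
#' @param noiseSd baseline noise SD (counts)
#' @param baseline constant baseline offset (counts)
#' @param transitionLabel label stored on the trace; defaults to the first
#'   peak's transition (both stereoisomers share one transition and are
#'   distinguished by retention time only)
#' @param seed integer seed for the baseline noise
#' @return a [ChromatogramTrace-class]
#' @examples
#' tr <- simulateTrace(list(peakModel(8.3, 5e4), peakModel(8.8, 5e3)),
#'                     from = 7.5, to = 9.5)
#' integratePeak(tr, c(8.2, 8.4))
#' @export
simulateTrace <- function(peaks, from = 0, to = 12.5, gridStep = 0.002,
                          noiseSd = 0, baseline = 0,
                          transitionLabel = NULL, seed = 1L) {
  if (is(peaks, "PeakModel")) peaks <- list(peaks)
  stopifnot(all(vapply(peaks, is, logical(1), "PeakModel")))
  if (gridStep <= 0) stop("gridStep must be > 0", call. = FALSE)
  if (to <= from) stop("'to' must exceed 'from'", call. = FALSE)
  times <- seq(from, to, by = gridStep)
  intens <- rep(baseline, length(times))
  for (p in peaks) intens <- intens + .peakShape(p, times)
  if (noiseSd > 0)
    intens <- withSeed(seed, intens + stats::rnorm(length(times), 0, noiseSd))
  intens <- pmax(intens, 0)
  lbl <- transitionLabel
  if (is.null(lbl))
    lbl <- if (length(peaks)) peaks[[1L]]@transitionLabel else .TRANSITION_ANALYTE
  new("ChromatogramTrace", times = times, intensities = intens,
      transitionLabel = lbl)
}

#' Integrate a peak in a retention-time window
#'
#' Trapezoidal integration of baseline-subtracted intensities; the baseline
#' is the linear segment between the window's endpoint intensities (classical
#' valley-to-valley baseline for a windowed MRM peak).
#'
#' @param trace a [ChromatogramTrace-class]
#' @param window numeric length-2, `(t_start, t_end)` in min with
#'   `t_start < t_end`, inside the trace's grid, spanning >= 3 grid points
#' @param baselineSubtract subtract the endpoint-to-endpoint baseline
#'   (default `TRUE`)
#' @return peak area (counts * min)
#' @examples
#' tr <- simulateTrace(peakModel(8.3, 1, sigma = 0.02), from = 8, to = 8.6)
#' integratePeak(tr, c(8.2, 8.4))   # ~ 1 * 0.02 * sqrt(2*pi)
#' @export
integratePeak <- function(trace, window, baselineSubtract = TRUE) {
  stopifnot(is(trace, "ChromatogramTrace"), length(window) == 2L)
  if (window[1L] >= window[2L]) stop("t_start must be < t_end", call. = FALSE)
  tt <- trace@times
  if (window[1L] < tt[1L] - 1e-9 || window[2L] > tt[length(tt)] + 1e-9)
    stop("integration window outside the time grid", call. = FALSE)
  idx <- which(tt >= window[1L] - 1e-9 & tt <= window[2L] + 1e-9)
  if (length(idx) < 3L)
    stop("integration window must span at least 3 grid points", call. = FALSE)
  x <- tt[idx]
  y <- trace@intensities[idx]
  if (baselineSubtract) {
    nb <- length(x)
    base <- y[1L] + (y[nb] - y[1L]) * (x - x[1L]) / (x[nb] - x[1L])
    y <- y - base
  }
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Chromatographic resolution between two peaks
#'
#' `Rs = 1.18 * |dRT| / (FWHM_a + FWHM_b)` with `FWHM = 2.3548 * sigma`,
#' the half-height resolution formula. `Rs >= 1.5` is conventionally taken
#' as baseline separation — the property that lets two co-monitored
#' stereoisomers on one MRM transition be quantified by window alone.
#'
#' @param peakA,peakB [PeakModel-class] objects
#' @return resolution (unitless)
#' @examples
#' peakResolution(peakModel(8.3, sigma = 0.05), peakModel(8.8, sigma = 0.05))
#' @export
peakResolution <- function(peakA, peakB) {
  stopifnot(is(peakA, "PeakModel"), is(peakB, "PeakModel"))
  fwhmA <- 2.3548 * peakA@sigma
  fwhmB <- 2.3548 * peakB@sigma
  if (fwhmA + fwhmB <= 0) stop("zero peak widths", call. = FALSE)
  1.18 * abs(peakA@retentionTime - peakB@retentionTime) / (fwhmA + fwhmB)
}

#' Default oxysterol peak panel
#'
#' The two stereoisomer peaks at their observed retention times (~8.3 min
#' for 4beta-OHC, ~8.8 min for 4alpha-OHC, shared transition 613.3>490.5)
#' and the deuterated internal standard (620.3>497.6, co-eluting with
#' 4beta-OHC). Peak heights default to areas proportional to typical
#' endogenous plasma levels; widths are chosen so the pair is
#' baseline-resolved.
#'
#' @param height4b,height4a,heightIS apex intensities (counts)
#' @param sigma shared Gaussian width (min)
#' @return named list of [PeakModel-class] objects
#' @export
oxysterolPeakPanel <- function(height4b = 5e4, height4a = 8.8e3,
                               heightIS = 5e4, sigma = 0.02) {
  list(`4b_OHC` = peakModel(8.3, height4b, sigma,
                            transitionLabel = .TRANSITION_ANALYTE),
       `4a_OHC` = peakModel(8.8, height4a, sigma,
                            transitionLabel = .TRANSITION_ANALYTE),
       IS = peakModel(8.3, heightIS, sigma,
                      transitionLabel = .TRANSITION_IS))
}

#' Write / read a chromatogram trace as two-column CSV
#'
#' @param trace a [ChromatogramTrace-class]
#' @param path file path
#' @param transitionLabel label to attach on reading
#' @return `readTrace` returns a [ChromatogramTrace-class];
#'   `writeTrace` returns `path` invisibly
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "ChromatogramTrace"))
  utils::write.csv(data.frame(time_min = trace@times,
                              intensity = trace@intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path, transitionLabel = .TRANSITION_ANALYTE) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "intensity") %in% names(df)))
    stop("trace CSV must have columns time_min, intensity", call. = FALSE)
  new("ChromatogramTrace", times = df$time_min,
      intensities = pmax(df$intensity, 0), transitionLabel = transitionLabel)
}
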
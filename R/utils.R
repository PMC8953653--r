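## Internal helpers shared by the generators and the pipeline.

## Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a per-stage seed from a base seed; kept inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

## Correlated proportional noise for (analyte, IS) area pairs. The per-area
## SD is scaled so that the first-order CV of the area *ratio* equals `cv`.
## Returns a list with multiplicative factors for both areas.
ratioNoiseFactors <- function(n, cv, rho) {
  if (cv <= 0) return(list(analyte = rep(1, n), is = rep(1, n)))
  sdArea <- cv / sqrt(2 * (1 - rho))
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(analyte = 1 + sdArea * z1, is = 1 + sdArea * z2)
}

## Zero-truncated normal by rejection; exact for the mild truncation used
## here (means several SDs above zero).
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

## Lognormal draws moment-matched to (mean, sd) on the natural scale.
rlnormMoment <- function(n, mean, sd) {
  if (mean <= 0) stop("lognormal family requires mean > 0", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## Expected analyte/IS area ratio at a concentration.
expectedRatio <- function(truth, conc) truth@intercept + truth@slopeRatio * conc

## Endogenous level of one analyte from the truth object.
endogenousLevel <- function(truth, analyte) {
  switch(analyte,
         "4b_OHC" = truth@endogenous4b,
         "4a_OHC" = truth@endogenous4a,
         stop("unknown analyte: ", analyte, call. = FALSE))
}

assertAnalytes <- function(analytes) {
  bad <- setdiff(analytes, .ANALYTES)
  if (length(bad))
    stop("unknown analyte(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.ANALYTES, collapse = ", "), ")", call. = FALSE)
  analytes
}
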
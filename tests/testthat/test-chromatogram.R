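test_that("gradient composition interpolates the binary gradient", {
  gp <- gradientProgram()
  expect_equal(gradientComposition(gp, 0.25), 80)          # initial hold
  expect_equal(gradientComposition(gp, 7.0), 95)           # inside the hold
  expect_equal(gradientComposition(gp, 3.25), 87.5)        # ramp midpoint
  # exact breakpoint values, continuity along a fine grid
  bp <- gp@breakpoints
  expect_equal(gradientComposition(gp, bp[, 1]), bp[, 2])
  tgrid <- seq(0, 12.5, by = 0.005)
  comp <- gradientComposition(gp, tgrid)
  expect_true(all(abs(diff(comp)) < 1))                    # no jumps on grid
  expect_error(gradientComposition(gp, 13), "runtime")
  expect_error(gradientComposition(gp, -0.1), "runtime")
})

test_that("simulated traces have Gaussian apexes, isomer separation and exact areas", {
  pk <- peakModel(8.3, height = 1000, sigma = 0.02)
  tr <- simulateTrace(pk, from = 8, to = 8.6, gridStep = 0.001)
  expect_equal(intensity(tr)[which.min(abs(rtime(tr) - 8.3))], 1000,
               tolerance = 1e-6)

  # two stereoisomer peaks resolve into two local maxima 0.5 min apart
  panel <- list(peakModel(8.3, 5e4, sigma = 0.02),
                peakModel(8.8, 5e3, sigma = 0.02))
  tr2 <- simulateTrace(panel, from = 7.5, to = 9.5, gridStep = 0.001)
  y <- intensity(tr2)
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  locmax <- locmax[y[locmax] > 100]
  expect_length(locmax, 2L)
  expect_equal(diff(rtime(tr2)[locmax]), 0.5, tolerance = 0.01)

  # Riemann sum equals the closed-form Gaussian area within 0.1%
  total <- sum(intensity(tr2)) * 0.001
  expect_equal(total, (5e4 + 5e3) * 0.02 * sqrt(2 * pi), tolerance = 1e-3)

  # empty peak list: baseline-only trace, not an error
  expect_s4_class(simulateTrace(list(), from = 0, to = 1), "ChromatogramTrace")
})

test_that("windowed trapezoidal integration matches the Gaussian closed form", {
  pk <- peakModel(8.3, height = 1, sigma = 0.02)
  tr <- simulateTrace(pk, from = 8, to = 8.6, gridStep = 0.0005)
  area <- integratePeak(tr, 8.3 + c(-5, 5) * 0.02, baselineSubtract = FALSE)
  expect_equal(area, 1 * 0.02 * sqrt(2 * pi), tolerance = 0.01)

  zero <- simulateTrace(list(), from = 0, to = 1, gridStep = 0.01)
  expect_equal(integratePeak(zero, c(0.2, 0.8)), 0)

  # linearity: doubling intensities doubles the area
  tr2 <- new("ChromatogramTrace", times = rtime(tr),
             intensities = 2 * intensity(tr), transitionLabel = "x")
  expect_equal(integratePeak(tr2, c(8.2, 8.4)),
               2 * integratePeak(tr, c(8.2, 8.4)))

  expect_error(integratePeak(tr, c(8.3, 8.3005)), "3 grid points")
  expect_error(integratePeak(tr, c(8.4, 8.2)), "t_start")
  expect_error(integratePeak(tr, c(7.0, 8.4)), "outside")
})

test_that("resolution formula and baseline-separation property hold", {
  a <- peakModel(8.3, sigma = 0.05)
  b <- peakModel(8.8, sigma = 0.05)
  expect_equal(peakResolution(a, a), 0)
  expect_equal(peakResolution(a, b), 1.18 * 0.5 / (2 * 2.3548 * 0.05))
  expect_equal(peakResolution(a, b), 2.5055, tolerance = 1e-3)
  # strictly increasing in |dRT| at fixed widths
  rs <- vapply(seq(8.35, 9.3, by = 0.05),
               function(rt) peakResolution(a, peakModel(rt, sigma = 0.05)),
               numeric(1))
  expect_true(all(diff(rs) > 0))

  # Rs >= 1.5: windowed integrals within 1% of isolated-peak areas
  p1 <- peakModel(8.3, 5e4, sigma = 0.02)
  p2 <- peakModel(8.8, 5e3, sigma = 0.02)
  expect_gt(peakResolution(p1, p2), 1.5)
  both <- simulateTrace(list(p1, p2), from = 7.5, to = 9.5, gridStep = 0.001)
  w1 <- 8.3 + c(-6, 6) * 0.02
  w2 <- 8.8 + c(-6, 6) * 0.02
  iso1 <- simulateTrace(p1, from = 7.5, to = 9.5, gridStep = 0.001)
  iso2 <- simulateTrace(p2, from = 7.5, to = 9.5, gridStep = 0.001)
  expect_equal(integratePeak(both, w1), integratePeak(iso1, w1),
               tolerance = 0.01)
  expect_equal(integratePeak(both, w2), integratePeak(iso2, w2),
               tolerance = 0.01)
})

test_that("traces round-trip through two-column CSV", {
  tr <- simulateTrace(oxysterolPeakPanel()[["4b_OHC"]], from = 8, to = 8.6,
                      gridStep = 0.002, noiseSd = 10, seed = 4)
  path <- tempfile(fileext = ".csv")
  writeTrace(tr, path)
  back <- readTrace(path)
  expect_equal(rtime(back), rtime(tr))
  expect_equal(intensity(back), intensity(tr))
})
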
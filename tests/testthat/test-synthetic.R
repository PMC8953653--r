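test_that("calibration run generator is linear, uses the printed ladder, and is seed-stable", {
  truth <- zeroNoiseTruth()
  run <- generateCalibrationRun(truth)
  expect_equal(run$level_ng_ml, c(0.5, 1, 2, 5, 20, 50, 200, 500))
  expect_equal(nrow(run), 8L)
  # noise-free linearity: ratio is exactly slope * level
  expect_equal(run$analyte_area / run$is_area, 0.01 * run$level_ng_ml)
  # level 500 alone -> ratio exactly 5.0
  one <- generateCalibrationRun(truth, levels = 500)
  expect_equal(one$analyte_area / one$is_area, 5.0, tolerance = 1e-12)
  expect_error(generateCalibrationRun(truth, levels = numeric(0)), "empty")
  expect_error(generateCalibrationRun(truth, levels = c(-1, 5)), "positive")

  noisy <- assayGroundTruth()
  expect_identical(generateCalibrationRun(noisy, seed = 7),
                   generateCalibrationRun(noisy, seed = 7))
  expect_false(identical(generateCalibrationRun(noisy, seed = 7),
                         generateCalibrationRun(noisy, seed = 8)))
})

test_that("validation batch generator counts, labels and back-calculates correctly", {
  truth <- assayGroundTruth()
  qc <- generateValidationBatches(truth, nBatches = 3, nReps = 6)
  expect_equal(sum(qc$analyte == "4b_OHC"), 3 * 5 * 6)
  expect_equal(sum(qc$analyte == "4a_OHC"), 3 * 5 * 6)
  expect_setequal(unique(qc$level_label),
                  c("endogenous", "LLOQ", "QCA", "QCB", "QCC"))
  # default non-blank spikes are the printed QC additions
  expect_equal(sort(unique(qc$spike_ng_ml[qc$spike_ng_ml > 0])),
               c(0.5, 1.5, 25, 400))
  expect_error(generateValidationBatches(truth, spikes = c(0, -1)), "negative")

  # zero-noise truth with endogenous 40.1: every QCB replicate back-calculates
  # to exactly 65.1 ng/ml through the noise-free response model
  t0 <- zeroNoiseTruth(endogenous4b = 40.1)
  qc0 <- generateValidationBatches(t0, analytes = "4b_OHC")
  cal0 <- generateCalibrationRun(t0)
  model <- fitCalibration(cal0$level_ng_ml, cal0$analyte_area / cal0$is_area)
  conc <- backCalculate(model, qc0$analyte_area / qc0$is_area)
  expect_equal(conc[qc0$level_label == "QCB"], rep(65.1, 18), tolerance = 1e-10)
})

test_that("recovery experiment encodes lot factors and arm algebra", {
  truth <- assayGroundTruth()
  tab <- generateRecoveryMatrixExperiment(truth)
  spiked <- tab[tab$design_arm != "blank_plasma", ]
  expect_equal(sum(spiked$analyte == "4b_OHC"), 6 * 3 * 3)
  expect_error(generateRecoveryMatrixExperiment(truth, arms = "mid_spike"),
               "unknown design_arm")

  # identity factors + zero noise: arms agree after endogenous subtraction
  t0 <- zeroNoiseTruth()
  tab0 <- generateRecoveryMatrixExperiment(t0, analytes = "4b_OHC")
  blank <- tab0$area[tab0$design_arm == "blank_plasma"][1]
  for (lev in c("QCA", "QCB", "QCC")) {
    d <- tab0[tab0$level_label == lev & tab0$lot == "lot1", ]
    pre <- d$area[d$design_arm == "pre_extraction_spike"] - blank
    post <- d$area[d$design_arm == "post_extraction_spike"] - blank
    neat <- d$area[d$design_arm == "neat_solution"]
    expect_equal(pre, post)
    expect_equal(post, neat)
  }

  # configured factors propagate exactly: matrix 110%, recovery 92%
  tf <- zeroNoiseTruth(matrixFactorPerLot = c(lotA = 1.10),
                       recoveryFactorPerLot = c(lotA = 0.92))
  tabf <- generateRecoveryMatrixExperiment(tf, nLots = 1, analytes = "4b_OHC")
  res <- assessRecoveryMatrix(tabf)
  expect_equal(res$recovery$recovery_pct, rep(92, 3), tolerance = 1e-10)
  expect_equal(res$matrix_effect$matrix_effect_pct, rep(110, 3),
               tolerance = 1e-10)
})

test_that("stability series follows the configured drift and counting", {
  t0 <- zeroNoiseTruth(betweenBatchCV = 0)
  # drift disabled (closed tubes): residual exactly 100% at all days
  ss0 <- generateStabilitySeries(t0, conditions = "closed_RT",
                                 betweenSubjectCV = 0)
  res0 <- stabilityAssessSeries(ss0)
  expect_equal(res0$residual_pct, rep(100, nrow(res0)))
  expect_true(all(res0$stable))

  truth <- assayGroundTruth()
  ss <- generateStabilitySeries(truth)
  expect_equal(sum(ss$analyte == "4b_OHC" & ss$day > 0), 6 * 4 * 5)
  res <- stabilityAssessSeries(ss)
  openRT <- res[res$condition == "open_RT" & res$analyte == "4b_OHC", ]
  expect_lt(openRT$residual_pct[openRT$day == 2], 85)
  expect_gt(openRT$residual_pct[openRT$day == 30], 115)
  expect_error(generateStabilitySeries(truth, days = c(2, 1, 7)),
               "strictly increasing")
  expect_error(generateStabilitySeries(truth, conditions = "vacuum"),
               "unknown storage condition")
})

test_that("cohort generator honours sizes, degenerate SDs and moment targets", {
  spec <- cohortSpec()
  cohort <- generateCohort(spec)
  expect_equal(nrow(cohort), 9 + 15 + 14)
  expect_equal(as.vector(table(cohort$group)[c("healthy", "CKD3_5", "CKD5D")]),
               c(9L, 15L, 14L))

  degenerate <- cohortSpec(sd4b = c(0, 0, 0), sd4a = c(0, 0, 0),
                           sdTC = c(0, 0, 0))
  dc <- generateCohort(degenerate)
  expect_equal(dc$conc_4b_ng_ml[dc$group == "healthy"], rep(23.6, 9))

  big <- cohortSpec(n = c(healthy = 5000L, CKD3_5 = 5000L, CKD5D = 5000L),
                    seed = 11L)
  bc <- generateCohort(big)
  for (g in c("healthy", "CKD3_5", "CKD5D")) {
    i <- bc$group == g
    j <- match(g, names(big@n))
    expect_equal(mean(bc$conc_4b_ng_ml[i]), big@mean4b[j], tolerance = 0.02)
    expect_equal(mean(bc$conc_4a_ng_ml[i]), big@mean4a[j], tolerance = 0.02)
    expect_equal(mean(bc$total_chol_mg_dl[i]), big@meanTC[j], tolerance = 0.02)
  }
  expect_error(cohortSpec(mean4a = c(-1, 5.9, 4.8), family = "lognormal"),
               "positive means")
})

test_that("every generator is deterministic under a fixed seed", {
  truth <- assayGroundTruth()
  spec <- cohortSpec()
  expect_identical(generateValidationBatches(truth, seed = 7),
                   generateValidationBatches(truth, seed = 7))
  expect_identical(generateRecoveryMatrixExperiment(truth, seed = 7),
                   generateRecoveryMatrixExperiment(truth, seed = 7))
  expect_identical(generateStabilitySeries(truth, seed = 7),
                   generateStabilitySeries(truth, seed = 7))
  expect_identical(generateCohort(spec, seed = 7),
                   generateCohort(spec, seed = 7))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- .Random.seed
  invisible(generateValidationBatches(truth))
  expect_identical(.Random.seed, before)
})

test_that("zero-noise unity-factor pipeline returns exact reference statistics", {
  t0 <- zeroNoiseTruth()
  cal <- generateCalibrationRun(t0)
  model <- fitCalibration(cal$level_ng_ml, cal$analyte_area / cal$is_area)
  qc <- generateValidationBatches(t0, analytes = "4b_OHC")
  qc$conc_ng_ml <- backCalculate(model, qc$analyte_area / qc$is_area)
  rep <- summarizeValidation(qc[, c("batch", "level_label", "spike_ng_ml",
                                    "replicate", "analyte", "conc_ng_ml")])
  spiked <- !is.na(rep@withinBatch$accuracy_pct)
  expect_equal(rep@withinBatch$accuracy_pct[spiked],
               rep(100, sum(spiked)), tolerance = 1e-9)
  expect_equal(rep@withinBatch$cv_pct, rep(0, nrow(rep@withinBatch)),
               tolerance = 1e-9)
  rm0 <- assessRecoveryMatrix(generateRecoveryMatrixExperiment(t0))
  expect_equal(rm0$recovery$recovery_pct,
               rep(100, nrow(rm0$recovery)), tolerance = 1e-9)
  expect_equal(rm0$matrix_effect$matrix_effect_pct,
               rep(100, nrow(rm0$matrix_effect)), tolerance = 1e-9)
})

test_that("back-calculated QC dispersion converges to the configured CV", {
  truth <- assayGroundTruth(cvProportional = 0.04, sdAdditive = 0)
  qc <- generateValidationBatches(truth, nBatches = 1, nReps = 2000,
                                  spikes = c(QCB = 25), analytes = "4b_OHC",
                                  seed = 3L)
  conc <- (qc$analyte_area / qc$is_area) / truth@slopeRatio
  # first-order ratio CV equals cvProportional; MC tolerance at n = 2000
  expect_equal(sd(conc) / mean(conc), 0.04, tolerance = 0.05)
})
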
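test_that("endogenous estimation is the blank-replicate mean", {
  expect_equal(estimateEndogenous(1:6), 3.5)
  expect_equal(estimateEndogenous(rep(40.1, 6)), 40.1)
  expect_error(estimateEndogenous(numeric(0)), "no blank")
  expect_error(estimateEndogenous(40.1), ">= 2")
})

test_that("background-addition accuracy uses nominal = endogenous + spike", {
  # perfect measurement: accuracy exactly 100
  expect_equal(accuracyBackgroundAddition(40.1 + 25, 40.1, 25), 100)
  # published worked cells reconstruct after 1-decimal rounding
  expect_equal(round(accuracyBackgroundAddition(67.0, 40.1, 25), 1), 102.9)
  expect_equal(round(accuracyBackgroundAddition(402.4, 37.1, 400), 1), 92.1)
  expect_error(accuracyBackgroundAddition(10, 5, 0), "spike")
  expect_error(accuracyBackgroundAddition(10, -1, 5), "endogenous")
})

test_that("precision is the sample-SD CV and is scale invariant", {
  expect_equal(precisionCV(c(9, 11)), 100 * sqrt(2) / 10)
  expect_equal(precisionCV(rep(3, 6)), 0)
  v <- c(4.1, 3.9, 4.4, 4.0)
  expect_equal(precisionCV(17.3 * v), precisionCV(v))
  expect_error(precisionCV(5), ">= 2")
  expect_error(precisionCV(c(-1, 1)), "zero mean")
})

test_that("batch-to-batch pooling reduces to within-batch on identical batches", {
  one <- data.frame(batch = 1, level_label = rep(c("endogenous", "QCB"), each = 6),
                    spike_ng_ml = rep(c(0, 25), each = 6), replicate = 1:6,
                    analyte = "4b_OHC",
                    conc_ng_ml = c(rep(40, 6), rep(65.5, 6)))
  three <- do.call(rbind, lapply(1:3, function(b) transform(one, batch = b)))
  b2b <- batchToBatchStats(three, "QCB")
  expect_equal(b2b$accuracy_pct, 100 * 65.5 / 65)
  expect_equal(b2b$cv_pct, 0)
  expect_equal(b2b$n, 18)
  # balanced all-100% batches pool to exactly 100%
  expect_equal(batchToBatchStats(transform(three, conc_ng_ml =
    ifelse(level_label == "QCB", 65, conc_ng_ml)), "QCB")$accuracy_pct, 100)
  expect_warning(batchToBatchStats(three[three$batch < 3 |
                                           three$level_label == "endogenous", ],
                                   "QCB"), "missing in batch")
})

test_that("pooled estimates recover configured bias and CV over repeated studies", {
  truth <- assayGroundTruth(cvProportional = 0.05, sdAdditive = 0,
                            betweenBatchCV = 0)
  accs <- cvs <- numeric(500)
  for (r in 1:500) {
    qc <- generateValidationBatches(truth, nBatches = 3, nReps = 6,
                                    spikes = c(endogenous = 0, QCB = 25),
                                    analytes = "4b_OHC", bias = 0.98,
                                    seed = 1000 + r)
    qc$conc_ng_ml <- (qc$analyte_area / qc$is_area) / truth@slopeRatio
    st <- batchToBatchStats(qc, "QCB")
    accs[r] <- st$accuracy_pct
    cvs[r] <- st$cv_pct
  }
  # blank reference is itself biased, so pooled accuracy is pulled toward
  # 100 by the endogenous share of the nominal; compare to the analytic value
  endo <- truth@endogenous4b
  expected <- 100 * (0.98 * (endo + 25)) / (0.98 * endo + 25)
  expect_equal(mean(accs), expected, tolerance = 0.01)
  expect_equal(mean(cvs), 5, tolerance = 0.1)
})

test_that("recovery and matrix-effect ratios report per-lot values with bracketing ranges", {
  rec <- apparentRecovery(c(92, 90, 95), c(100, 100, 100))
  expect_equal(rec$per_lot, c(92, 90, 95))
  expect_equal(rec$mean, 92.33333, tolerance = 1e-6)
  expect_true(rec$min <= rec$mean && rec$mean <= rec$max)
  expect_equal(apparentRecovery(100, 100)$mean, 100)
  expect_error(apparentRecovery(c(1, 2), c(1, 0)), "zero post")

  me <- matrixEffect(c(110, 85), 100)
  expect_equal(me$per_lot, c(110, 85))
  expect_equal(matrixEffect(100, 100)$mean, 100)
  expect_error(matrixEffect(1, 0), "zero neat")

  # generator ground truth flows through the estimator within noise
  truth <- assayGroundTruth(seed = 21L)
  res <- assessRecoveryMatrix(generateRecoveryMatrixExperiment(truth))
  recTruth <- 100 * mean(truth@recoveryFactorPerLot)
  meTruth <- 100 * mean(truth@matrixFactorPerLot)
  expect_equal(mean(res$recovery$recovery_pct), recTruth, tolerance = 0.03)
  expect_equal(mean(res$matrix_effect$matrix_effect_pct), meTruth,
               tolerance = 0.03)
  agg <- unique(res$recovery[, c("analyte", "level_label", "mean_pct",
                                 "min_pct", "max_pct")])
  expect_true(all(agg$min_pct <= agg$mean_pct & agg$mean_pct <= agg$max_pct))
})

test_that("stability classification is inclusive at 85 and 115 percent", {
  res <- stabilityAssess(c(100, 84.9, 85, 115, 115.1), 100)
  expect_equal(res$residual_pct, c(100, 84.9, 85, 115, 115.1))
  expect_equal(res$stable, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_error(stabilityAssess(100, 0), "reference")
  expect_error(stabilityAssess(100, 100, window = c(115, 85)), "window")
})

test_that("stress-test accuracy mirrors background addition with degradation", {
  t0 <- zeroNoiseTruth(endogenous4b = 40)
  qc <- generateValidationBatches(t0, nBatches = 1,
                                  spikes = c(endogenous = 0, QCB = 25),
                                  analytes = "4b_OHC")
  conc <- (qc$analyte_area / qc$is_area) / t0@slopeRatio
  unstressed <- freezeThawAutosamplerAccuracy(
    conc[qc$level_label == "QCB"], 40, 25)
  expect_equal(unstressed, 100, tolerance = 1e-9)

  deg <- generateValidationBatches(t0, nBatches = 1,
                                   spikes = c(endogenous = 0, QCB = 25),
                                   analytes = "4b_OHC", bias = 0.95)
  dconc <- (deg$analyte_area / deg$is_area) / t0@slopeRatio
  degraded <- freezeThawAutosamplerAccuracy(
    dconc[deg$level_label == "QCB"], 40, 25)
  expect_equal(degraded, 95, tolerance = 1e-9)
})

test_that("validation report has the three-batch + pooled structure and sane ledgers", {
  truth <- assayGroundTruth()
  cal <- generateCalibrationRun(truth)
  models <- list(`4b_OHC` = fitCalibration(cal$level_ng_ml,
                                           cal$analyte_area / cal$is_area))
  qc <- generateValidationBatches(truth, analytes = "4b_OHC")
  conc <- backCalculateBatches(qc, models)
  rep <- summarizeValidation(conc)
  wb <- rep@withinBatch
  expect_equal(sort(unique(wb$batch)), 1:3)
  expect_equal(nrow(wb), 3 * 5)            # 3 within-batch blocks x 5 levels
  expect_equal(nrow(rep@batchToBatch), 5)  # one pooled block
  expect_equal(nrow(rep@endogenous), 3)
  expect_true(all(wb$cv_pct >= 0))
  expect_true(all(wb$accuracy_pct[!is.na(wb$accuracy_pct)] > 0))
  # each accuracy derives from its own batch's endogenous mean
  qcb <- wb[wb$level_label == "QCB", ]
  for (i in seq_len(nrow(qcb))) {
    e <- rep@endogenous$endogenous_ng_ml[rep@endogenous$batch == qcb$batch[i]]
    expect_equal(qcb$accuracy_pct[i],
                 accuracyBackgroundAddition(qcb$mean_ng_ml[i], e, 25))
  }
})
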
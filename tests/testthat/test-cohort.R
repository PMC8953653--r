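test_that("ratio derivation matches hand arithmetic and rejects zero denominators", {
  rec <- data.frame(subject_id = "x", group = "healthy",
                    conc_4b_ng_ml = 23.6, conc_4a_ng_ml = 3.6,
                    total_chol_mg_dl = 160.0)
  out <- deriveRatios(rec)
  expect_equal(out$ratio_4b_4a, 23.6 / 3.6)          # ~6.56
  expect_equal(out$ratio_4b_4a, 6.5556, tolerance = 1e-4)
  expect_equal(out$ratio_4a_tc, 3.6 / 160)
  expect_equal(deriveRatios(transform(rec, conc_4a_ng_ml = 23.6))$ratio_4b_4a, 1)
  # stage-5D scale check: 4.8 ng/ml over 160 mg/dl -> 0.030
  expect_equal(round(deriveRatios(transform(rec, conc_4a_ng_ml = 4.8))$ratio_4a_tc, 3),
               0.030)
  expect_error(deriveRatios(transform(rec, total_chol_mg_dl = 0)), "denominator")
})

test_that("one-way ANOVA agrees with the sum-of-squares oracle and t^2 identity", {
  g3 <- list(c(23.1, 25.2, 22.8, 24.0), c(31.5, 29.2, 33.1), c(21.9, 22.5, 23.3, 24.1, 22.0))
  res <- oneWayAnova(g3)
  expect_equal(res@statistic, bruteForceF(g3), tolerance = 1e-10)
  set.seed(8)
  for (i in 1:20) {
    g <- lapply(sample(2:5, 3, TRUE) + 1, rnorm)
    expect_equal(oneWayAnova(g)@statistic, bruteForceF(g), tolerance = 1e-10)
  }
  # identical groups: F = 0, p = 1
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(oneWayAnova(same)@statistic, 0)
  expect_equal(oneWayAnova(same)@pValue, 1)
  # two groups: F equals the squared pooled t statistic
  a <- rnorm(8); b <- rnorm(10, 0.5)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(oneWayAnova(list(a, b))@statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(oneWayAnova(list(a, b))@pValue, tt$p.value, tolerance = 1e-10)
})

test_that("Dunnett adjusted p-values sit between raw and Bonferroni and match multcomp", {
  set.seed(31)
  g <- list(healthy = rnorm(9, 23.6, 7.4), CKD3_5 = rnorm(15, 31.2, 10.3),
            CKD5D = rnorm(14, 22.7, 6.7))
  res <- dunnettPosthoc(g, controlIndex = 1)
  ph <- res@posthoc
  expect_true(all(ph$p_adjusted >= ph$p_raw - 1e-9))
  expect_true(all(ph$p_adjusted <= pmin(1, 2 * ph$p_raw) + 1e-6))

  # independent cross-check against multcomp's Dunnett contrasts
  library(multcomp)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(names(g), lengths(g)), levels = names(g)))
  glt <- glht(aov(y ~ grp, data = df), linfct = mcp(grp = "Dunnett"))
  pm <- summary(glt, test = adjusted("single-step"))$test$pvalues
  expect_equal(ph$p_adjusted, as.numeric(pm), tolerance = 1e-3)

  # identical groups: adjusted p ~ 1
  same <- list(c(1, 2, 3, 2), c(1, 2, 3, 2), c(1, 2, 3, 2))
  expect_true(all(dunnettPosthoc(same)@posthoc$p_adjusted > 0.999))
  # k = 2: single comparison degenerates to the plain two-sample t test
  two <- list(a = rnorm(8), b = rnorm(9, 1))
  tt <- t.test(two$a, two$b, var.equal = TRUE)
  expect_equal(dunnettPosthoc(two)@posthoc$p_adjusted, tt$p.value,
               tolerance = 1e-9)
  expect_error(dunnettPosthoc(g, controlIndex = 5), "out of range")
})

test_that("Kruskal-Wallis H matches the rank oracle and is rank invariant", {
  set.seed(12)
  for (i in 1:20) {
    g <- lapply(sample(3:8, 3, TRUE), function(n) round(rnorm(n), 1))  # ties
    res <- kruskalWallisDunn(g)
    expect_equal(res@statistic, bruteForceH(g), tolerance = 1e-10)
  }
  g <- list(c(2.1, 3.5, 1.2, 4.4), c(5.1, 6.0, 4.9), c(0.5, 0.9, 1.4, 0.2))
  h1 <- kruskalWallisDunn(g)@statistic
  h2 <- kruskalWallisDunn(lapply(g, function(x) exp(x)))@statistic
  expect_equal(h1, h2, tolerance = 1e-12)
  # identical groups: H = 0; fully degenerate data flagged with p = 1
  expect_equal(kruskalWallisDunn(list(1:4, 1:4, 1:4))@statistic, 0,
               tolerance = 1e-12)
  deg <- kruskalWallisDunn(list(rep(2, 3), rep(2, 4)))
  expect_equal(deg@pValue, 1)
  expect_match(deg@method, "degenerate")
  # Dunn adjustment never lowers p-values
  dn <- kruskalWallisDunn(g, pAdjust = "bonferroni")@posthoc
  expect_true(all(dn$p_adjusted >= dn$p_raw - 1e-12))
})

test_that("full cohort analysis runs all endpoints and detects the 4a elevation at large n", {
  res <- runCohortAnalysis(generateCohort(cohortSpec(seed = 2L)))
  expect_setequal(names(res$tests), names(defaultEndpointTests()))
  expect_equal(res$tests$ratio_4a_tc@testName, "Kruskal-Wallis")
  expect_equal(res$tests$conc_4b@testName, "one-way ANOVA")
  expect_equal(nrow(res$summary), 3 * 5)

  # power check at large n: the 4a endpoint is significant, CKD3-5 > healthy
  big <- cohortSpec(n = c(healthy = 200L, CKD3_5 = 200L, CKD5D = 200L),
                    seed = 3L)
  resBig <- runCohortAnalysis(generateCohort(big))
  t4a <- resBig$tests$conc_4a
  expect_lt(t4a@pValue, 0.001)
  row <- t4a@posthoc[t4a@posthoc$comparison == "CKD3_5 - healthy", ]
  expect_true(row$significant)
  expect_gt(row$estimate, 0)

  single <- generateCohort(cohortSpec())
  expect_error(runCohortAnalysis(single[single$group == "healthy", ]),
               ">= 2 groups")
  expect_error(runCohortAnalysis(single, control = "nope"), "not present")
})
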
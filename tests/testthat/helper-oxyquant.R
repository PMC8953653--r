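# Shared fixtures and independent oracles.

# Noise-free, factor-free ground truth: the whole pipeline must be exact.
zeroNoiseTruth <- function(...) {
  args <- list(...)
  defaults <- list(cvProportional = 0, sdAdditive = 0, betweenBatchCV = 0,
                   matrixFactorPerLot = c(lot1 = 1, lot2 = 1, lot3 = 1,
                                          lot4 = 1, lot5 = 1, lot6 = 1),
                   recoveryFactorPerLot = c(lot1 = 1, lot2 = 1, lot3 = 1,
                                            lot4 = 1, lot5 = 1, lot6 = 1))
  do.call(assayGroundTruth, utils::modifyList(defaults, args))
}

# Brute-force weighted-least-squares oracle: numerical minimisation of the
# weighted SSE, independent of the closed-form/lm route.
bruteForceWLS <- function(x, y, w) {
  sse <- function(p) sum(w * (y - p[1] - p[2] * x)^2)
  start <- c(mean(y), (y[length(y)] - y[1]) / (x[length(x)] - x[1]))
  fit <- optim(start, sse, method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 50000))
  fit2 <- optim(fit$par, sse, method = "BFGS",
                control = list(reltol = 1e-16, maxit = 10000))
  c(intercept = fit2$par[1], slope = fit2$par[2])
}

# Direct sum-of-squares one-way ANOVA F oracle.
bruteForceF <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups); N <- length(all)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Direct rank-formula Kruskal-Wallis H oracle with tie correction.
bruteForceH <- function(groups) {
  all <- unlist(groups)
  N <- length(all)
  r <- rank(all)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(all)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
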
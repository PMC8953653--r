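#' @include AllClasses.R utils.R
NULL

#' Derive cholesterol-normalised and isomer ratios
#'
#' Adds the three derived endpoints to a cohort table: 4beta-OHC over total
#' cholesterol, 4alpha-OHC over total cholesterol (both in (ng/ml)/(mg/dl),
#' the scale on which population values are ~0.02–0.03), and the unitless
#' 4beta/4alpha ratio. The cholesterol-normalised 4beta ratio is the
#' classical CYP3A phenotyping index; the 4beta/4alpha ratio additionally
#' cancels the shared autoxidation component of both stereoisomers.
#'
#' @param records cohort `data.frame` with columns `conc_4b_ng_ml`,
#'   `conc_4a_ng_ml`, `total_chol_mg_dl` (all > 0)
#' @return the table with added columns `ratio_4b_tc`, `ratio_4a_tc`,
#'   `ratio_4b_4a`
#' @examples
#' deriveRatios(generateCohort(cohortSpec()))[1:3, ]
#' @export
deriveRatios <- function(records) {
  need <- c("conc_4b_ng_ml", "conc_4a_ng_ml", "total_chol_mg_dl")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(records$total_chol_mg_dl <= 0) || any(records$conc_4a_ng_ml <= 0))
    stop("zero or negative denominator in ratio derivation", call. = FALSE)
  records$ratio_4b_tc <- records$conc_4b_ng_ml / records$total_chol_mg_dl
  records$ratio_4a_tc <- records$conc_4a_ng_ml / records$total_chol_mg_dl
  records$ratio_4b_4a <- records$conc_4b_ng_ml / records$conc_4a_ng_ml
  records
}

.asGroupList <- function(groups) {
  if (!is.list(groups)) stop("groups must be a list of numeric vectors", call. = FALSE)
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  lapply(groups, as.numeric)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects between/within decomposition (equal-variance
#' F test).
#'
#' @param groups list of numeric vectors, one per group, each `n >= 2`
#' @return a [GroupComparison-class] with empty post-hoc table
#' @examples
#' oneWayAnova(list(rnorm(9, 23.6, 7.4), rnorm(15, 31.2, 10.3),
#'                  rnorm(14, 22.7, 6.7)))
#' @export
oneWayAnova <- function(groups) {
  groups <- .asGroupList(groups)
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  new("GroupComparison", testName = "one-way ANOVA",
      statistic = unname(ht$statistic),
      parameter = ht$parameter,
      pValue = unname(ht$p.value),
      posthoc = data.frame(), method = "none")
}

#' Dunnett's many-to-one comparisons
#'
#' Compares every group against a designated control using the multivariate
#' t distribution of the simultaneous t statistics. The exact correlation
#' structure for (possibly unbalanced) group sizes is used:
#' `rho_ij = lambda_i * lambda_j` with `lambda_i = sqrt(n_i / (n_i + n_0))`,
#' on `N - k` error degrees of freedom from the pooled one-way variance.
#' The multivariate-t probability is evaluated by quasi-Monte-Carlo
#' quadrature under a fixed internal seed, so results are reproducible.
#' Adjusted p-values are monotone in |t|, never below the raw two-sample
#' p-value, and never above its Bonferroni correction.
#'
#' @param groups list of numeric vectors, one per group
#' @param controlIndex index of the control group within `groups` (default 1)
#' @param alpha significance level for the `significant` flag (default 0.05)
#' @return a [GroupComparison-class]; the omnibus slot carries the ANOVA F
#'   and the post-hoc table the Dunnett-adjusted p-values
#' @examples
#' g <- list(control = rnorm(9), a = rnorm(15, 1), b = rnorm(14))
#' dunnettPosthoc(g, controlIndex = 1)
#' @export
dunnettPosthoc <- function(groups, controlIndex = 1L, alpha = 0.05) {
  groups <- .asGroupList(groups)
  k <- length(groups)
  if (controlIndex < 1L || controlIndex > k)
    stop("control_index out of range", call. = FALSE)
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_len(k))
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  sse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  df <- N - k
  mse <- sse / df
  treat <- setdiff(seq_len(k), controlIndex)
  n0 <- n[controlIndex]
  tstat <- (means[treat] - means[controlIndex]) /
    sqrt(mse * (1 / n[treat] + 1 / n0))
  lam <- sqrt(n[treat] / (n[treat] + n0))
  R <- outer(lam, lam); diag(R) <- 1
  m <- length(treat)
  pAdj <- vapply(seq_len(m), function(i) {
    q <- abs(tstat[i])
    if (m == 1L)  # single comparison: no multiplicity, plain two-sided t
      return(2 * stats::pt(q, df, lower.tail = FALSE))
    ## quasi-Monte-Carlo quadrature under a fixed internal seed so repeated
    ## calls are bit-reproducible
    prob <- withSeed(20061001L,
      mvtnorm::pmvt(lower = rep(-q, m), upper = rep(q, m), df = df, corr = R,
                    algorithm = mvtnorm::GenzBretz(abseps = 1e-7,
                                                   maxpts = 50000L)))
    min(max(1 - as.numeric(prob), 0), 1)
  }, numeric(1))
  pRaw <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  ph <- data.frame(
    comparison = paste(nms[treat], "-", nms[controlIndex]),
    estimate = means[treat] - means[controlIndex],
    statistic = tstat,
    p_raw = pRaw,
    p_adjusted = pmax(pAdj, pRaw),
    row.names = NULL, stringsAsFactors = FALSE)
  ph$significant <- ph$p_adjusted < alpha
  om <- oneWayAnova(groups)
  new("GroupComparison", testName = "one-way ANOVA",
      statistic = om@statistic, parameter = om@parameter,
      pValue = om@pValue, posthoc = ph,
      method = "Dunnett (multivariate t)")
}

#' Kruskal-Wallis test with Dunn's post-hoc z tests
#'
#' Rank-based omnibus H statistic with tie correction, followed by Dunn's
#' pairwise z tests on mean ranks. The p-adjustment for the Dunn tests
#' defaults to none (raw z p-values) and can be set to any method of
#' [stats::p.adjust()]; the choice is recorded in the output. When every
#' observation is identical the H statistic is undefined and the omnibus
#' p-value is reported as 1 with a degenerate-method flag.
#'
#' @param groups list of numeric vectors, one per group
#' @param pAdjust p-adjustment for the Dunn comparisons (default `"none"`)
#' @param alpha significance level for the `significant` flag
#' @param comparisons `"all"` for all pairs, or the index of a control
#'   group for many-to-one comparisons
#' @return a [GroupComparison-class]
#' @examples
#' kruskalWallisDunn(list(rnorm(9), rnorm(15, 1), rnorm(14)))
#' @export
kruskalWallisDunn <- function(groups, pAdjust = "none", alpha = 0.05,
                              comparisons = "all") {
  groups <- .asGroupList(groups)
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), lengths(groups)))
  if (length(unique(values)) == 1L) {
    return(new("GroupComparison", testName = "Kruskal-Wallis",
               statistic = 0, parameter = c(df = k - 1),
               pValue = 1, posthoc = data.frame(),
               method = "degenerate: all observations identical"))
  }
  ht <- stats::kruskal.test(values, g)
  ## Dunn z statistics on mean ranks with tie correction
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tieCorr
  pairs <- if (identical(comparisons, "all")) {
    utils::combn(k, 2L, simplify = FALSE)
  } else {
    ctrl <- as.integer(comparisons)
    if (ctrl < 1L || ctrl > k) stop("control index out of range", call. = FALSE)
    lapply(setdiff(seq_len(k), ctrl), function(i) c(ctrl, i))
  }
  z <- vapply(pairs, function(p) {
    (rbar[p[2L]] - rbar[p[1L]]) / sqrt(sigma2 * (1 / n[p[1L]] + 1 / n[p[2L]]))
  }, numeric(1))
  pRaw <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  pAdj <- stats::p.adjust(pRaw, method = pAdjust)
  ph <- data.frame(
    comparison = vapply(pairs, function(p) paste(nms[p[2L]], "-", nms[p[1L]]),
                        character(1)),
    statistic = unname(z),
    p_raw = unname(pRaw),
    p_adjusted = unname(pAdj),
    row.names = NULL, stringsAsFactors = FALSE)
  ph$significant <- ph$p_adjusted < alpha
  new("GroupComparison", testName = "Kruskal-Wallis",
      statistic = unname(ht$statistic), parameter = ht$parameter,
      pValue = unname(ht$p.value), posthoc = ph,
      method = paste0("Dunn (adjust: ", pAdjust, ")"))
}

#' Default endpoint-to-test mapping of the cohort analysis
#'
#' Concentration endpoints and the 4beta/4alpha ratio use one-way ANOVA
#' with Dunnett's many-to-one test; the cholesterol-normalised 4alpha
#' endpoint uses Kruskal-Wallis with Dunn's test (its population
#' distribution is visibly skewed at small n).
#'
#' @return named character vector endpoint -> `"anova_dunnett"` or
#'   `"kruskal_dunn"`
#' @export
defaultEndpointTests <- function() {
  c(conc_4b = "anova_dunnett",
    ratio_4b_tc = "anova_dunnett",
    conc_4a = "anova_dunnett",
    ratio_4a_tc = "kruskal_dunn",
    ratio_4b_4a = "anova_dunnett")
}

.endpointColumn <- c(conc_4b = "conc_4b_ng_ml", conc_4a = "conc_4a_ng_ml",
                     ratio_4b_tc = "ratio_4b_tc", ratio_4a_tc = "ratio_4a_tc",
                     ratio_4b_4a = "ratio_4b_4a")

#' Run the full three-group cohort analysis
#'
#' Derives the ratio endpoints, summarises each endpoint per group
#' (mean +/- SD) and applies the endpoint-specific omnibus + post-hoc test
#' with the designated control group.
#'
#' @param records cohort `data.frame` (columns `subject_id`, `group`,
#'   `conc_4b_ng_ml`, `conc_4a_ng_ml`, `total_chol_mg_dl`)
#' @param control name of the control group (default `"healthy"`)
#' @param alpha significance level (default 0.05)
#' @param endpointTests endpoint -> test mapping, default
#'   [defaultEndpointTests()]
#' @param dunnAdjust p-adjustment for Dunn comparisons (default `"none"`)
#' @return list with `summary` (per group x endpoint mean, SD, n) and
#'   `tests` (named list of [GroupComparison-class] per endpoint)
#' @examples
#' res <- runCohortAnalysis(generateCohort(cohortSpec()))
#' res$tests$conc_4a
#' @export
runCohortAnalysis <- function(records, control = "healthy", alpha = 0.05,
                              endpointTests = defaultEndpointTests(),
                              dunnAdjust = "none") {
  if (!"group" %in% names(records))
    stop("cohort table must have a 'group' column", call. = FALSE)
  grps <- unique(records$group)
  if (length(grps) < 2L)
    stop("need >= 2 groups present in the cohort", call. = FALSE)
  if (!control %in% grps)
    stop("control group '", control, "' not present", call. = FALSE)
  records <- deriveRatios(records)
  ## control first so many-to-one comparisons read naturally
  grps <- c(control, setdiff(grps, control))
  tests <- list(); summ <- list()
  for (ep in names(endpointTests)) {
    col <- .endpointColumn[[ep]]
    byGroup <- lapply(grps, function(g) records[[col]][records$group == g])
    names(byGroup) <- grps
    summ[[length(summ) + 1L]] <- data.frame(
      endpoint = ep, group = grps,
      n = lengths(byGroup),
      mean = vapply(byGroup, mean, numeric(1)),
      sd = vapply(byGroup, stats::sd, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
    tests[[ep]] <- switch(endpointTests[[ep]],
      anova_dunnett = dunnettPosthoc(byGroup, controlIndex = 1L, alpha = alpha),
      kruskal_dunn = kruskalWallisDunn(byGroup, pAdjust = dunnAdjust,
                                       alpha = alpha, comparisons = 1L),
      stop("unknown test tag: ", endpointTests[[ep]], call. = FALSE))
  }
  list(summary = do.call(rbind, summ), tests = tests)
}
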
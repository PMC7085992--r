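cohortFrame <- function(values, times = NULL, events = NULL) {
  n <- length(values)
  data.frame(subject_id = seq_len(n), v = values,
             followup_months = if (is.null(times)) rep(10, n) else times,
             event = if (is.null(events)) rep(1L, n) else events)
}

test_that("median split uses the order-statistic midpoint, ties to low", {
  ms <- medianSplit(cohortFrame(c(1, 2, 3, 4)), "v")
  expect_equal(ms$median, 2.5)
  expect_equal(ms$low$v, c(1, 2))
  expect_equal(ms$high$v, c(3, 4))
  expect_equal(ms$indicator, c(0L, 0L, 1L, 1L))

  tied <- medianSplit(cohortFrame(c(1, 2, 2, 5)), "v")
  expect_equal(tied$median, 2)
  expect_equal(nrow(tied$low), 3)        # ties at the median go low

  expect_error(medianSplit(cohortFrame(rep(4, 6)), "v"), "degenerate")
})

test_that("an even cohort splits into two equal halves", {
  set.seed(2)
  ms <- medianSplit(cohortFrame(rnorm(56, 0.76, 0.2)), "v")
  expect_equal(nrow(ms$low), 28)
  expect_equal(nrow(ms$high), 28)
})

test_that("mortality rate reproduces printed-table rounding", {
  expect_equal(mortalityRate(28, 4), 14L)
  expect_equal(mortalityRate(56, 21), 37L)   # 37.5 prints as 37
  expect_equal(mortalityRate(28, 17), 61L)
  expect_equal(mortalityRate(40, 0), 0L)
  expect_error(mortalityRate(0, 0), "nPatients")
  expect_error(mortalityRate(5, 6), "<=")
})

test_that("Kaplan-Meier matches the hand product-limit and the ECDF", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_true(all(diff(km$surv) <= 0))

  kmC <- kmEstimate(c(2, 4, 7), c(0, 0, 0))
  expect_true(all(kmC$surv == 1))

  set.seed(4)
  tt <- rexp(40)
  kmE <- kmEstimate(tt, rep(1L, 40))
  for (i in seq_along(kmE$time))
    expect_equal(kmE$surv[i], 1 - ecdf(tt)(kmE$time[i]))
  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank agrees with the exhaustive hypergeometric oracle", {
  set.seed(8)
  checked <- 0L
  for (rep in 1:60) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    t1 <- sample(1:6, n1, TRUE); t2 <- sample(1:6, n2, TRUE)
    e1 <- rbinom(n1, 1, 0.8); e2 <- rbinom(n2, 1, 0.8)
    if (sum(e1) + sum(e2) == 0) next
    oracle <- logrankOracle(t1, e1, t2, e2)
    if (is.na(oracle)) next
    lr <- logrankTest(t1, e1, t2, e2)
    expect_equal(lr$chiSquare, oracle, tolerance = 1e-8)
    expect_equal(lr$pValue, pchisq(oracle, 1, lower.tail = FALSE))
    # rank invariance under time rescaling
    lr2 <- logrankTest(2 * t1, e1, 2 * t2, e2)
    expect_equal(lr2$chiSquare, lr$chiSquare, tolerance = 1e-12)
    checked <- checked + 1L
  }
  expect_gt(checked, 30)

  ident <- logrankTest(c(1, 3, 5), c(1, 1, 0), c(1, 3, 5), c(1, 1, 0))
  expect_equal(ident$chiSquare, 0, tolerance = 1e-12)
  expect_equal(ident$pValue, 1)
  expect_error(logrankTest(1:3, rep(0, 3), 1:3, rep(0, 3)), "zero events")
})

test_that("univariate Cox recovers a two-group hazard ratio", {
  sim <- simulateCoxCoverage(nRep = 30, n = 300, hr = 2, seed = 10)
  expect_gt(sim$coverage, 0.85)
  expect_equal(sim$meanLogHR, log(2), tolerance = 0.12)
  # null covariate: log HR near 0
  sim0 <- simulateCoxCoverage(nRep = 30, n = 500, hr = 1, seed = 11)
  expect_gt(mean(abs(log(sim0$hrs)) < 0.2), 0.9)
})

test_that("univariate Cox flags separation and rejects degenerate input", {
  ch <- data.frame(v = c(rep(0, 10), rep(10, 10)),
                   followup_months = c(rexp(10, 1), rexp(10, 0.1)),
                   event = c(rep(1L, 10), rep(0L, 10)))
  fit <- coxUnivariate(ch, "v")
  expect_true(fit$flagged)
  expect_match(fit$diagnostic, "separation|converge|infinit")
  chC <- data.frame(v = rep(1, 10), followup_months = rexp(10),
                    event = rep(1L, 10))
  expect_error(coxUnivariate(chC, "v"), "degenerate|identical")
  chE <- data.frame(v = rnorm(10), followup_months = rexp(10),
                    event = rep(0L, 10))
  expect_error(coxUnivariate(chE, "v"), "event")
})

test_that("backward elimination honours the removal threshold", {
  ch <- generateCohort(n = 120, logHR = c(spinal_cord_n_suv = log(6)),
                       seed = 21)
  bk <- coxBackward(ch)
  expect_true("spinal_cord_n_suv" %in% bk$retained)
  # every removal happened at LRT p above the threshold
  if (nrow(bk$steps)) expect_true(all(bk$steps$lrt_p > 0.1))
  # every survivor's final LRT p is at or below it
  if (nrow(bk$result)) expect_true(all(bk$result$lrt_p <= 0.1))

  # a single strong variable is retained unchanged
  single <- coxBackward(ch, variables = "spinal_cord_n_suv")
  expect_equal(single$retained, "spinal_cord_n_suv")
  expect_equal(nrow(single$steps), 0)
})

test_that("pure-noise cohorts keep each variable only rarely", {
  kept <- integer(0)
  for (s in 1:25) {
    ch <- generateCohort(n = 56, seed = 300 + s)
    kept <- c(kept, length(coxBackward(ch)$retained))
  }
  expect_lt(mean(kept) / 7, 0.2)   # per-variable retention near removal_p
})

test_that("t tests and least squares match closed forms", {
  x <- c(1.1, 2.0, 2.9, 4.2, 5.0)
  same <- compareGroups(x, x)
  expect_equal(same$tStatistic, 0)
  expect_equal(same$pValue, 1)
  expect_error(compareGroups(rep(1, 5), rep(2, 5)), "zero variance")

  lf <- linFit(x, 2 * x)
  expect_equal(lf$slope, 2)
  expect_equal(lf$r, 1)
  y <- c(2.3, 2.9, 4.4, 5.0, 6.1)
  lf2 <- linFit(x, y)
  # normal equations by hand
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(lf2$slope, sl)
  expect_equal(lf2$intercept, mean(y) - sl * mean(x))
  expect_equal(lf2$r, cor(x, y))
  expect_equal(lf2$pValue, cor.test(x, y)$p.value)
})

test_that("the outcome table reproduces subgroup counts exactly", {
  ch <- generateCohort(n = 56, logHR = c(psoas_vc_suv_pct = log(4)),
                       seed = 33)
  tab <- outcomeTable(ch)
  uni <- tab$univariate
  expect_equal(nrow(uni), 14)
  for (v in strataVariables()) {
    ms <- medianSplit(ch, v)
    for (grp in c("low", "high")) {
      row <- uni[uni$variable == v & uni$group == grp, ]
      expect_equal(row$n, nrow(ms[[grp]]))
      expect_equal(row$deaths, sum(ms[[grp]]$event))
      expect_equal(row$mortality_pct,
                   mortalityRate(nrow(ms[[grp]]), sum(ms[[grp]]$event)))
    }
    expect_true(is.na(uni[uni$variable == v & uni$group == "low",
                          "hazard_ratio"]))
  }
})

test_that("the proportionality hook returns a Schoenfeld table", {
  ch <- generateCohort(n = 100, logHR = c(ba4_suv = log(2)), seed = 5)
  fit <- coxUnivariate(ch, "ba4_suv")
  z <- schoenfeldCheck(fit$fit)
  expect_s3_class(z, "cox.zph")
})
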
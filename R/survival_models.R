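# Prognostic stratification: median splits, KM / log-rank, univariate and
# backward-eliminated multivariate Cox models, and the cohort summary
# table. Model fitting is delegated to the survival package (Breslow tie
# handling); the split rules, the step-down LRT procedure and the report
# arithmetic are implemented here.

#' The seven stratification variables of the cohort analysis
#'
#' Age, ALS functional score (ALSFRS-R), spinal cord N-SUV, psoas volume
#' per IBW, psoas N-SUV, psoas VC-SUV, and motor cortex (BA4) SUV.
#' @return character vector of cohort-table column names.
#' @export
strataVariables <- function() {
  c("age_years", "alsfrs_r", "spinal_cord_n_suv", "psoas_volume_mL_per_kg",
    "psoas_n_suv", "psoas_vc_suv_pct", "ba4_suv")
}

#' Split a cohort at the median of one variable
#'
#' The median is the midpoint of the order statistics for even n. Ties at
#' the median go to the low group, so low = values \code{<=} median and
#' high = values \code{>} median.
#'
#' @param records cohort data.frame.
#' @param variable column name to split on.
#' @return list with \code{low}, \code{high} (row subsets), \code{median},
#'   and \code{indicator} (integer 0 = low, 1 = high, aligned to
#'   \code{records}).
#' @export
medianSplit <- function(records, variable) {
  v <- records[[variable]]
  if (is.null(v)) stop("input error: no column '", variable, "'")
  v <- as.numeric(v)
  if (sum(is.finite(v)) < 2L)
    stop("input error: need >= 2 finite values to split")
  med <- stats::median(v[is.finite(v)])
  if (all(v[is.finite(v)] == v[is.finite(v)][1]))
    stop("degenerate split error: all values of '", variable,
         "' are identical")
  ind <- as.integer(v > med)
  list(low = records[v <= med, , drop = FALSE],
       high = records[v > med, , drop = FALSE],
       median = med, indicator = ind)
}

#' Mortality rate as a printed percentage
#'
#' \code{100 * nDeaths / nPatients} rounded to the nearest integer, halves
#' rounded down (matching the convention of the reference cohort table,
#' where 21/56 prints as 37\%).
#'
#' @param nPatients,nDeaths counts with \code{0 <= nDeaths <= nPatients}.
#' @return integer percent.
#' @examples
#' mortalityRate(28, 4)   # 14
#' mortalityRate(56, 21)  # 37
#' @export
mortalityRate <- function(nPatients, nDeaths) {
  if (!isTRUE(all(nPatients > 0)))
    stop("input error: nPatients must be > 0")
  if (any(nDeaths < 0 | nDeaths > nPatients))
    stop("input error: need 0 <= nDeaths <= nPatients")
  as.integer(ceiling(100 * nDeaths / nPatients - 0.5))
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator with right censoring (event = 0 reduces the
#' risk set without a step).
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1 = death, 0 = censored).
#' @return list of class \code{"kmCurve"}: \code{time}, \code{surv},
#'   \code{nRisk}, \code{nEvent}, and the underlying
#'   \code{survival::survfit} object as \code{fit}.
#' @export
kmEstimate <- function(times, events) {
  if (length(times) == 0L) stop("input error: empty input")
  if (any(times < 0)) stop("input error: negative times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
                 nEvent = fit$n.event, fit = fit), class = "kmCurve")
}

#' @export
print.kmCurve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "time points,",
      sum(x$nEvent), "events\n")
  invisible(x)
}

#' @param x a \code{kmCurve}.
#' @param ... passed to \code{plot.survfit}.
#' @rdname kmEstimate
#' @export
plot.kmCurve <- function(x, ...) plot(x$fit, ...)

#' Log-rank test between two samples
#'
#' Standard log-rank statistic (hypergeometric expectation and variance at
#' each distinct event time), referred to a chi-square with 1 df.
#'
#' @param times1,events1 first group.
#' @param times2,events2 second group.
#' @return list with \code{chiSquare} and \code{pValue}.
#' @export
logrankTest <- function(times1, events1, times2, events2) {
  if (length(times1) == 0L || length(times2) == 0L)
    stop("input error: both groups must be nonempty")
  if (sum(events1) + sum(events2) == 0)
    stop("input error: log-rank undefined with zero events")
  tt <- c(times1, times2)
  ee <- c(events1, events2)
  gg <- rep(0:1, c(length(times1), length(times2)))
  sd <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  list(chiSquare = unname(sd$chisq),
       pValue = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

.coxResult <- function(fit, names) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(variable = names,
             hazard_ratio = unname(co[, "exp(coef)"]),
             ci95_low = unname(ci[, "lower .95"]),
             ci95_high = unname(ci[, "upper .95"]),
             p_value = unname(co[, "Pr(>|z|)"]),
             log_hr = unname(co[, "coef"]),
             se_log_hr = unname(co[, "se(coef)"]),
             row.names = NULL)
}

#' Univariate Cox model on a median-split indicator
#'
#' Proportional-hazards fit of death incidence on the binary above-median
#' indicator of one variable (Breslow tie handling, Wald 95\% CI).
#' Setting \code{continuous = TRUE} fits the variable untransformed
#' instead.
#'
#' @param records cohort data.frame with \code{followup_months} and
#'   \code{event} columns.
#' @param variable column to model.
#' @param continuous fit the raw variable instead of the indicator.
#' @return list with \code{result} (one-row data.frame: hazard_ratio,
#'   ci95_low/high, p_value, log_hr, se_log_hr), \code{median} (NA when
#'   continuous), \code{logLik}, \code{flagged}, \code{diagnostic}, and the
#'   \code{fit}.
#' @export
coxUnivariate <- function(records, variable, continuous = FALSE) {
  if (sum(records$event) < 1L)
    stop("input error: need at least one event")
  if (continuous) {
    x <- as.numeric(records[[variable]])
    med <- NA_real_
  } else {
    ms <- medianSplit(records, variable)
    x <- ms$indicator
    med <- ms$median
  }
  if (length(unique(x)) < 2L)
    stop("input error: degenerate design, '", variable, "' is constant")
  flagged <- FALSE
  diagnostic <- ""
  if (!continuous) {
    evt <- tapply(records$event, x, sum)
    if (any(evt == 0)) {
      flagged <- TRUE
      diagnostic <- "separation: one group has no events"
    }
  }
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(records$followup_months, records$event) ~ x,
      ties = "breslow"),
    warning = function(w) {
      flagged <<- TRUE
      diagnostic <<- paste(diagnostic, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(result = .coxResult(fit, variable), median = med,
       logLik = unname(fit$loglik[2]), flagged = flagged,
       diagnostic = trimws(diagnostic), fit = fit)
}

.coxMulti <- function(records, vars, continuous = FALSE) {
  X <- sapply(vars, function(v) {
    if (continuous) as.numeric(records[[v]])
    else medianSplit(records, v)$indicator
  })
  X <- as.matrix(X)
  df <- data.frame(X)
  names(df) <- vars
  df$.time <- records$followup_months
  df$.event <- records$event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(vars, collapse = " + ")))
  suppressWarnings(survival::coxph(fml, data = df, ties = "breslow"))
}

#' Backward elimination of a multivariate Cox model by likelihood ratio
#'
#' Starts from the model with all \code{variables} (as median-split
#' indicators by default) and iteratively removes the variable with the
#' largest likelihood-ratio-test p value while that p exceeds
#' \code{removalP}. The LRT for a variable compares the current model with
#' the model refitted without it (1 df). An empty final model is a valid
#' outcome.
#'
#' @param records cohort data.frame.
#' @param variables character vector (default the seven stratification
#'   variables, [strataVariables()]).
#' @param removalP removal threshold on the LRT p (default 0.1).
#' @param continuous fit raw variables instead of indicators.
#' @return list with \code{retained} (character), \code{result}
#'   (data.frame of HR/CI/p for retained variables; zero rows when empty),
#'   \code{steps} (data.frame log of removals: step, removed, lrt_p),
#'   \code{logLik}, \code{flagged}.
#' @export
coxBackward <- function(records, variables = strataVariables(),
                        removalP = 0.1, continuous = FALSE) {
  if (sum(records$event) < 1L)
    stop("input error: need at least one event")
  vars <- variables
  steps <- list()
  flagged <- FALSE
  step <- 0L
  while (length(vars) > 0L) {
    fit <- .coxMulti(records, vars, continuous)
    ll <- fit$loglik[2]
    lrtP <- vapply(vars, function(v) {
      rest <- setdiff(vars, v)
      ll0 <- if (length(rest) == 0L) fit$loglik[1] else
        .coxMulti(records, rest, continuous)$loglik[2]
      stats::pchisq(2 * (ll - ll0), df = 1, lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(lrtP)
    if (lrtP[worst] <= removalP) break
    step <- step + 1L
    steps[[step]] <- data.frame(step = step, removed = vars[worst],
                                lrt_p = unname(lrtP[worst]))
    vars <- vars[-worst]
  }
  if (length(vars) > 0L) {
    fit <- .coxMulti(records, vars, continuous)
    res <- .coxResult(fit, vars)
    res$lrt_p <- vapply(vars, function(v) {
      rest <- setdiff(vars, v)
      ll0 <- if (length(rest) == 0L) fit$loglik[1] else
        .coxMulti(records, rest, continuous)$loglik[2]
      stats::pchisq(2 * (fit$loglik[2] - ll0), df = 1, lower.tail = FALSE)
    }, numeric(1))
    ll <- unname(fit$loglik[2])
  } else {
    res <- data.frame(variable = character(0), hazard_ratio = numeric(0),
                      ci95_low = numeric(0), ci95_high = numeric(0),
                      p_value = numeric(0), log_hr = numeric(0),
                      se_log_hr = numeric(0), lrt_p = numeric(0))
    ll <- NA_real_
  }
  list(retained = vars, result = res,
       steps = if (length(steps)) do.call(rbind, steps) else
         data.frame(step = integer(0), removed = character(0),
                    lrt_p = numeric(0)),
       logLik = ll, flagged = flagged)
}

#' Two-group comparison and least-squares regression
#'
#' \code{compareGroups} is the Student t test (paired or unpaired; Welch
#' variant available); \code{linFit} is ordinary least squares with the
#' Pearson correlation and its p value.
#'
#' @param values1,values2 numeric vectors (equal length when paired).
#' @param paired paired test (default FALSE).
#' @param welch use the Welch unequal-variance variant (default FALSE).
#' @return \code{compareGroups}: list(tStatistic, pValue, df);
#'   \code{linFit}: list(slope, intercept, r, pValue).
#' @export
compareGroups <- function(values1, values2, paired = FALSE, welch = FALSE) {
  if (length(values1) < 2L || length(values2) < 2L)
    stop("input error: need >= 2 values per group")
  if (stats::var(values1) == 0 && stats::var(values2) == 0)
    stop("input error: zero variance in both groups")
  tt <- stats::t.test(values1, values2, paired = paired,
                      var.equal = !welch && !paired)
  list(tStatistic = unname(tt$statistic), pValue = tt$p.value,
       df = unname(tt$parameter))
}

#' @param x,y regression input vectors.
#' @rdname compareGroups
#' @export
linFit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("input error: need equal-length x, y with n >= 3")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  n <- length(x)
  # t test on Pearson r (guard the perfect-fit limit)
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r = r, pValue = p)
}

#' Schoenfeld-residual proportionality hook
#'
#' Thin wrapper over \code{survival::cox.zph} for users who want to check
#' the proportional-hazards assumption of a fitted model.
#'
#' @param coxFit a \code{coxph} fit (e.g. \code{$fit} of
#'   [coxUnivariate()]).
#' @return the \code{cox.zph} table.
#' @export
schoenfeldCheck <- function(coxFit) survival::cox.zph(coxFit)

#' Cohort outcome table: median-split subgroups with univariate Cox
#'
#' For each variable: the two median-split subgroups with their sizes,
#' death counts and mortality rates, and the univariate hazard ratio of
#' the above-median group (below-median as reference); plus the
#' backward-eliminated multivariate model. This reproduces the layout of
#' the reference cohort's predictive-power table from any cohort table.
#'
#' @param records cohort data.frame with \code{followup_months},
#'   \code{event} and the variables.
#' @param variables character vector (default [strataVariables()]).
#' @param removalP multivariate removal threshold (default 0.1).
#' @return list with \code{univariate} (data.frame: variable, median,
#'   group, n, deaths, mortality_pct, hazard_ratio, ci95_low, ci95_high,
#'   p_value — HR columns NA on the reference rows) and
#'   \code{multivariate} (the [coxBackward()] output).
#' @export
outcomeTable <- function(records, variables = strataVariables(),
                         removalP = 0.1) {
  rows <- list()
  for (v in variables) {
    ms <- medianSplit(records, v)
    un <- coxUnivariate(records, v)
    for (grp in c("low", "high")) {
      sub <- ms[[grp]]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, median = ms$median, group = grp, n = nrow(sub),
        deaths = sum(sub$event),
        mortality_pct = mortalityRate(nrow(sub), sum(sub$event)),
        hazard_ratio = if (grp == "high") un$result$hazard_ratio else NA,
        ci95_low = if (grp == "high") un$result$ci95_low else NA,
        ci95_high = if (grp == "high") un$result$ci95_high else NA,
        p_value = if (grp == "high") un$result$p_value else NA)
    }
  }
  list(univariate = do.call(rbind, rows),
       multivariate = coxBackward(records, variables, removalP))
}
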
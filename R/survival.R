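#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator with right censoring (censored subjects count
#' as at risk through their censoring time), Greenwood variance and the
#' median survival time (first time at which S drops to 0.5 or below;
#' `NA` when the curve never reaches 0.5). Computed with the `survival`
#' package's product-limit machinery.
#'
#' @param cohort_group `data.frame` with `time_months` and `event`.
#' @return object of class `km_curve` with `time` (event-time grid),
#'   `surv`, `n_risk`, `n_event`, `greenwood_var`, `median`.
#' @export
km_estimate <- function(cohort_group) {
  time <- cohort_group$time_months
  event <- cohort_group$event
  if (any(time <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "plain")
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 greenwood_var = (fit$surv * fit$std.err)^2,
                 median = med),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km a [km_estimate()] result.
#' @param t times (same units as the fit).
#' @return survival probabilities (step function, right-continuous; 1
#'   before the first event time).
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1L))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", length(x$time), " time points, median ",
      if (is.na(x$median)) "not reached" else
        sprintf("%.2f months", x$median), "\n", sep = "")
  invisible(x)
}

#' Two-group log-rank test with hazard ratio
#'
#' Mantel-Cox log-rank statistic over the pooled event times, with the
#' hazard ratio reported in the KM-plot O/E convention
#' `HR = (O_A / E_A) / (O_B / E_B)` and a log-scale confidence interval
#' `exp(log HR +/- z * sqrt(1/E_A + 1/E_B))`. Note the O/E form computes
#' expectations under the null and is therefore conservative (biased
#' toward 1) for hazard ratios far from 1; use [cox_fit()] when an
#' unbiased estimate of a large effect is needed.
#'
#' @param group_a,group_b `data.frame`s with `time_months` and `event`.
#' @param conf_level confidence level for the HR interval.
#' @return object of class `logrank_result` with `chisq`, `p_value`
#'   (1 df), `observed`, `expected` (A then B), `hazard_ratio` (A vs B),
#'   `hr_ci`, `flagged` (TRUE when no events occurred).
#' @export
logrank_test <- function(group_a, group_b, conf_level = 0.95) {
  if (!nrow(group_a) || !nrow(group_b))
    stop("both groups need at least one subject")
  time <- c(group_a$time_months, group_b$time_months)
  event <- c(group_a$event, group_b$event)
  grp <- factor(rep(c("A", "B"), c(nrow(group_a), nrow(group_b))),
                levels = c("A", "B"))
  if (sum(event) == 0L)
    return(structure(list(chisq = NA_real_, p_value = NA_real_,
                          observed = c(0, 0),
                          expected = c(NA_real_, NA_real_),
                          hazard_ratio = NA_real_,
                          hr_ci = c(NA_real_, NA_real_), flagged = TRUE),
                     class = "logrank_result"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  obs <- as.numeric(sd_$obs)
  expd <- as.numeric(sd_$exp)
  hr <- (obs[1L] / expd[1L]) / (obs[2L] / expd[2L])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(1 / expd[1L] + 1 / expd[2L])
  structure(list(chisq = sd_$chisq,
                 p_value = stats::pchisq(sd_$chisq, df = 1L,
                                         lower.tail = FALSE),
                 observed = obs, expected = expd,
                 hazard_ratio = hr,
                 hr_ci = exp(log(hr) + c(-1, 1) * z * se_log),
                 flagged = FALSE),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf(
    "Log-rank: chisq = %.4f, p = %.3g; HR (O/E form) = %.4f [%.3f, %.3f]\n",
    x$chisq, x$p_value, x$hazard_ratio, x$hr_ci[1L], x$hr_ci[2L]))
  invisible(x)
}

#' Median (50%) split of a metric
#'
#' Splits subjects at the sample median into "low" and "high" groups of
#' as equal size as possible: subjects are ordered by value (ties broken
#' by original position, so the split is deterministic) and the first
#' `ceiling(n / 2)` form the low group. With distinct values this is
#' exactly the below/above-median split.
#'
#' @param values numeric vector, length >= 2.
#' @return list with integer index vectors `low` and `high`.
#' @export
median_split <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to split")
  ord <- order(values)                      # stable: ties keep input order
  n_low <- ceiling(n / 2)
  list(low = sort(ord[seq_len(n_low)]),
       high = sort(ord[(n_low + 1L):n]))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson fit with Breslow tie handling (via
#' `survival::coxph`). Aliased (collinear) covariates or non-convergence
#' set `flagged` and suppress coefficient reporting.
#'
#' @param cohort cohort `data.frame` (needs `time_months`, `event` and
#'   the covariate columns).
#' @param covariate_names character vector of covariate columns.
#' @return object of class `cox_fit_result` with `coef` (log hazard
#'   ratios), `se`, `p_value`, `converged`, `flagged`.
#' @export
cox_fit <- function(cohort, covariate_names) {
  if (sum(cohort$event) < 2L) stop("need at least 2 events")
  covs <- cohort[, covariate_names, drop = FALSE]
  if (!all(vapply(covs, function(c_) all(is.finite(as.numeric(c_))),
                  logical(1L))))
    stop("covariates must be finite")
  dat <- cbind(data.frame(.time = cohort$time_months,
                          .event = cohort$event), covs)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariate_names), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "breslow",
                    control = survival::coxph.control(iter.max = 50L)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(fml, data = dat, ties = "breslow",
                        control = survival::coxph.control(iter.max = 50L)))
      attr(f, "warned") <- TRUE
      f
    })
  cf <- stats::coef(fit)
  aliased <- any(is.na(cf))
  warned <- isTRUE(attr(fit, "warned"))
  converged <- !aliased && !warned
  sm <- summary(fit)
  nc <- length(covariate_names)
  nas <- stats::setNames(rep(NA_real_, nc), covariate_names)
  structure(list(
    coef = if (converged)
      stats::setNames(unname(cf), covariate_names) else nas,
    se = if (converged)
      stats::setNames(unname(sm$coefficients[, "se(coef)"]),
                      covariate_names) else nas,
    p_value = if (converged)
      stats::setNames(unname(sm$coefficients[, "Pr(>|z|)"]),
                      covariate_names) else nas,
    converged = converged,
    flagged = !converged),
    class = "cox_fit_result")
}

#' @export
print.cox_fit_result <- function(x, ...) {
  if (x$flagged) {
    cat("Cox fit: flagged (non-convergence or collinearity); no coefficients reported\n")
  } else {
    cat("Cox fit (Breslow ties):\n")
    for (i in seq_along(x$coef))
      cat(sprintf("  %s: beta = %.4f (HR %.4f), se %.4f, p = %.3g\n",
                  names(x$coef)[i], x$coef[i], exp(x$coef[i]), x$se[i],
                  x$p_value[i]))
  }
  invisible(x)
}

#' Ordinary least-squares line fit
#'
#' @param x,y numeric vectors (>= 3 points, `var(x) > 0`).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}

#' Normalize one cohort's c/s ratios to another's mean
#'
#' Multiplies `cohort$cs_ratio` by `mean(reference$cs_ratio) /
#' mean(cohort$cs_ratio)`, the harmonization used when pooling cohorts
#' whose tract metrics come from different scanners.
#'
#' @param cohort,reference cohort `data.frame`s.
#' @return `cohort` with rescaled `cs_ratio`.
#' @export
normalize_cs_to <- function(cohort, reference) {
  m <- mean(cohort$cs_ratio)
  if (m == 0) stop("cohort has zero mean cs_ratio")
  cohort$cs_ratio <- cohort$cs_ratio * mean(reference$cs_ratio) / m
  cohort
}

#' Exclude very short survivors
#'
#' Mirrors the clinical-analysis convention of dropping subjects who
#' survived less than one week (~0.23 months); off by default for
#' synthetic cohorts.
#'
#' @param cohort cohort `data.frame`.
#' @param min_months minimum retained survival time.
#' @return filtered cohort.
#' @export
exclude_short_survivors <- function(cohort, min_months = 7 / 30.44) {
  cohort[cohort$time_months >= min_months, , drop = FALSE]
}
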
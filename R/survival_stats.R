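## Survival machinery shared by every stage: Kaplan-Meier curves, log-rank
## tests, univariate Cox models, median splits and BH adjustment. All model
## fitting is delegated to the survival package; these wrappers fix the
## conventions used throughout (Efron ties, Wald p-values, 95% CIs).

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of S(t). Censored subjects leave the risk set after
#' their time; at tied times deaths are processed before censorings (the
#' standard convention).
#'
#' @param times follow-up times, non-negative.
#' @param events event indicators, 0 = censored, 1 = event.
#' @param endpoint endpoint label carried along (`"OS"`, `"PFS"`, `"PPS"`).
#' @return an object of class `"surv_curve"`: a list with `time` (starting at
#'   0), `survival` (starting at 1, non-increasing), `at_risk`, `n`, `events`,
#'   `median` (smallest time with S(t) <= 0.5, NA if never reached) and
#'   `endpoint`.
#' @export
km_estimate <- function(times, events, endpoint = "OS") {
  if (any(times < 0)) stop("negative follow-up time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (!length(times)) stop("at least one subject required")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(
    time = c(0, fit$time),
    survival = c(1, fit$surv),
    at_risk = c(length(times), fit$n.risk),
    n = length(times),
    events = sum(events),
    median = unname(summary(fit)$table["median"]),
    endpoint = endpoint
  ), class = "surv_curve")
}

#' @export
print.surv_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve (%s): n = %d, events = %d, median = %s\n",
              x$endpoint, x$n, x$events,
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

#' @export
plot.surv_curve <- function(x, ..., xlab = "time", ylab = "survival") {
  graphics::plot(x$time, x$survival, type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' @param times,events as in [km_estimate()].
#' @param groups group labels, one per subject; every group must be non-empty.
#' @return list with `chi2`, `df` (groups - 1) and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("at least two groups required")
  if (any(table(groups) == 0)) stop("empty group")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling. Reports the hazard ratio
#' per unit of the covariate, its 95% Wald confidence interval and Wald
#' p-value. Monotone partial likelihood (perfect separation) is flagged
#' rather than treated as an error.
#'
#' @param covariate numeric covariate, one value per subject, non-constant.
#' @param times,events as in [km_estimate()].
#' @return list with `coef` (log hazard ratio), `se`, `hr`, `ci_low`,
#'   `ci_high`, `p`, and `flagged` (TRUE when the fit looks separated or did
#'   not converge cleanly).
#' @export
cox_univariate <- function(covariate, times, events) {
  if (length(unique(covariate)) < 2) stop("constant covariate")
  if (sum(events) < 1) stop("no events in cohort")
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = "efron",
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(times, events) ~ covariate,
                        ties = "efron",
                        control = survival::coxph.control(iter.max = 100)))
      attr(f, "triomics_flag") <- TRUE
      f
    })
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  flagged <- isTRUE(attr(fit, "triomics_flag")) || !is.finite(beta) ||
    !is.finite(se) || abs(beta) > 15 || se > 100
  list(coef = beta, se = se, hr = exp(beta),
       ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
       p = 2 * stats::pnorm(-abs(beta / se)),
       flagged = flagged)
}

#' Median split into high/low groups
#'
#' `"high"` = strictly above the median, `"low"` = at or below it (ties at
#' the median deterministically go to `"low"`).
#'
#' @param values numeric vector with at least two distinct values.
#' @return character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(values) {
  if (length(unique(values)) < 2) stop("all values identical; cannot split")
  ifelse(values > stats::median(values), "high", "low")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, returned in input order and capped at 1.
#'
#' @param pvals p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
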
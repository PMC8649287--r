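#' Exact (Garwood) Poisson confidence interval for a count
#'
#' Chi-square inversion: `lower = qchisq(alpha/2, 2k)/2`,
#' `upper = qchisq(1 - alpha/2, 2k + 2)/2`, with `lower = 0` when `k = 0`.
#' Bounds are on the Poisson mean; divide by person-time for a rate.
#'
#' @param count non-negative event count (vectorised).
#' @param conf confidence level (default 0.95).
#' @return matrix with columns `lower`, `upper`.
#' @export
exact_poisson_ci <- function(count, conf = 0.95) {
  if (any(count < 0)) stop("count must be non-negative")
  if (any(count != floor(count))) stop("count must be integer-valued")
  a <- 1 - conf
  lower <- ifelse(count == 0, 0, stats::qchisq(a / 2, 2 * count) / 2)
  upper <- stats::qchisq(1 - a / 2, 2 * count + 2) / 2
  cbind(lower = lower, upper = upper)
}

#' Incidence table by exposure group and outcome
#'
#' For every outcome and exposure group: first-event count, person-time at
#' risk (each subject contributes follow-up to that outcome's first event or
#' censoring), rate per 1000 person-years, and the exact Poisson CI of the
#' rate (normal approximation on the log rate behind `method = "normal"`).
#'
#' @param outcomes long table with `subject_id`, `outcome`, `time_years`,
#'   `event` (as produced by [make_outcome_table()]).
#' @param groups factor of exposure groups, one entry per subject, named by
#'   (or ordered as) the unique subject ids in `outcomes`.
#' @param conf confidence level.
#' @param method `"exact"` (Garwood, default) or `"normal"` (log-rate
#'   approximation).
#' @return data.frame: `outcome`, `group`, `events`, `person_years`, `rate`,
#'   `ci_low`, `ci_high` (rates per 1000 person-years).
#' @export
incidence_table <- function(outcomes, groups, conf = 0.95,
                            method = c("exact", "normal")) {
  method <- match.arg(method)
  ids <- unique(outcomes$subject_id)
  if (is.null(names(groups))) {
    if (length(groups) != length(ids))
      stop("groups must be named by subject id or match the subjects")
    names(groups) <- as.character(ids)
  }
  g <- groups[as.character(outcomes$subject_id)]
  if (any(is.na(g))) stop("missing group assignment for some subjects")

  agg <- stats::aggregate(cbind(events = outcomes$event,
                                person_years = outcomes$time_years),
                          by = list(outcome = outcomes$outcome, group = g),
                          FUN = sum)
  if (any(agg$person_years <= 0)) stop("a group has zero person-time")
  rate <- 1000 * agg$events / agg$person_years
  if (method == "exact") {
    ci <- exact_poisson_ci(agg$events, conf)
    lo <- 1000 * ci[, "lower"] / agg$person_years
    hi <- 1000 * ci[, "upper"] / agg$person_years
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- 1 / sqrt(pmax(agg$events, 0.5))
    lo <- rate * exp(-z * se)
    hi <- rate * exp(z * se)
  }
  out <- data.frame(outcome = agg$outcome, group = agg$group,
                    events = agg$events, person_years = agg$person_years,
                    rate = rate, ci_low = lo, ci_high = hi)
  out[order(out$outcome, out$group), ]
}
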
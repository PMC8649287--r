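#' Assign the five usual-variability exposure groups
#'
#' Half-open intervals: `<10`, `[10,12)`, `[12,14)`, `[14,16)`, `>=16` mm Hg.
#'
#' @param usual_sd positive usual SBP variability values (mm Hg).
#' @return factor with levels `<10`, `10-11.9`, `12-13.9`, `14-15.9`,
#'   `>=16`.
#' @export
assign_variability_group <- function(usual_sd) {
  if (any(!is.finite(usual_sd) | usual_sd <= 0))
    stop("usual_sd must be positive and finite")
  cut(usual_sd, breaks = c(0, 10, 12, 14, 16, Inf), right = FALSE,
      labels = c("<10", "10-11.9", "12-13.9", "14-15.9", ">=16"))
}

#' Split follow-up into attained-age episodes (Lexis expansion)
#'
#' Partitions each subject's follow-up at half-decade boundaries of attained
#' age, producing counting-process rows with both the half-decade band
#' (45-49, ..., 80-84) and the decade age-at-risk band (45-54, ..., 75-84).
#' Attained age at or above 85 remains in the top band. Person-time and
#' events are conserved exactly.
#'
#' @param data data.frame with one row per subject, containing `age`
#'   (baseline age, years), `time_years` (follow-up) and `event` (0/1), plus
#'   any covariate columns, which are carried onto every episode.
#' @param age_var,time_var,event_var column names.
#' @return data.frame of episodes: all input columns plus `entry_age`,
#'   `exit_age`, `tstart`, `tstop` (time-on-study), `event` (on the last
#'   episode only), `half_decade_band`, `age_band`.
#' @export
lexis_split <- function(data, age_var = "age", time_var = "time_years",
                        event_var = "event") {
  age0 <- data[[age_var]]
  fu <- data[[time_var]]
  ev <- data[[event_var]]
  if (any(fu < 0)) stop("negative follow-up time")
  if (any(fu == 0)) stop("zero follow-up time; drop such subjects first")

  cuts <- seq(50, 80, by = 5)
  pieces <- lapply(seq_len(nrow(data)), function(i) {
    bnd <- cuts[cuts > age0[i] & cuts < age0[i] + fu[i]]
    entry <- c(age0[i], bnd)
    exit <- c(bnd, age0[i] + fu[i])
    k <- length(entry)
    cbind(row = i, entry_age = entry, exit_age = exit,
          event = c(rep(0, k - 1), ev[i]))
  })
  ep <- as.data.frame(do.call(rbind, pieces))
  out <- data[ep$row, setdiff(names(data), event_var), drop = FALSE]
  out$entry_age <- ep$entry_age
  out$exit_age <- ep$exit_age
  out$tstart <- ep$entry_age - age0[ep$row]
  out$tstop <- ep$exit_age - age0[ep$row]
  out$event <- as.integer(ep$event)
  hd <- pmin(pmax(45 + 5 * floor((out$entry_age - 45) / 5), 45), 80)
  out$half_decade_band <- factor(sprintf("%d-%d", hd, hd + 4),
                                 levels = sprintf("%d-%d", seq(45, 80, 5),
                                                  seq(45, 80, 5) + 4))
  dec <- 45 + 10 * ((hd - 45) %/% 10)
  out$age_band <- factor(sprintf("%d-%d", dec, dec + 9),
                         levels = sprintf("%d-%d", seq(45, 75, 10),
                                          seq(45, 75, 10) + 9))
  rownames(out) <- NULL
  out
}

#' Fit a counting-process Cox model
#'
#' Maximises the partial likelihood (Efron ties by default, Breslow optional)
#' over the episode rows produced by [lexis_split()], adjusting for the given
#' covariates. The timescale is time-on-study with the attained-age band as a
#' time-varying categorical covariate (include `"age_band"` or
#' `"half_decade_band"` among `covariates`), or attained age itself with
#' `timescale = "age"`.
#'
#' @param episodes episode data.frame with `tstart`, `tstop` (or `entry_age`,
#'   `exit_age` for the age timescale) and `event`.
#' @param covariates character vector of model terms (may include
#'   interactions, e.g. `"usual_sd:half_decade_band"`).
#' @param ties `"efron"` or `"breslow"`.
#' @param timescale `"study"` (default) or `"age"`.
#' @return object of class `bpv_cox`: list with `coefficients`, `vcov`,
#'   `loglik` (null and maximised), `ties`, `n_events`, `n`, `fit` (the
#'   underlying [survival::coxph()] object).
#' @export
fit_cox <- function(episodes, covariates, ties = c("efron", "breslow"),
                    timescale = c("study", "age")) {
  ties <- match.arg(ties)
  timescale <- match.arg(timescale)
  if (sum(episodes$event) < 1) stop("no events in the data")
  plain <- covariates[!grepl("[:*()]", covariates)]
  for (v in plain) {
    x <- episodes[[v]]
    if (is.null(x)) stop("covariate not found: ", v)
    if (length(unique(x[!is.na(x)])) < 2)
      stop("constant covariate: ", v)
  }
  resp <- if (timescale == "study") "survival::Surv(tstart, tstop, event)"
          else "survival::Surv(entry_age, exit_age, event)"
  fml <- stats::as.formula(paste(resp, "~", paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = episodes, ties = ties,
                         control = survival::coxph.control(
                           eps = 1e-12, toler.chol = 1e-13, iter.max = 100))
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15))
    warning("possible monotone likelihood (separation): extreme coefficients")
  structure(list(coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                 loglik = fit$loglik, ties = ties, n_events = fit$nevent,
                 n = fit$n, fit = fit),
            class = "bpv_cox")
}

#' @export
print.bpv_cox <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): %d rows, %d events\n", x$ties, x$n, x$n_events))
  print(round(cbind(coef = x$coefficients,
                    se = sqrt(diag(x$vcov))), 4))
  invisible(x)
}

#' Hazard ratio per 5 mm Hg of a linear exposure
#'
#' @param fit a [fit_cox()] result with the exposure entered linearly
#'   (per mm Hg).
#' @param term coefficient name of the exposure.
#' @param scale exposure increment (default 5 mm Hg).
#' @param conf confidence level.
#' @return named list: `hr`, `lo`, `hi`, `log_hr`, `se` (on the `scale`
#'   increment).
#' @export
per5_continuous_hr <- function(fit, term = "usual_sd", scale = 5,
                               conf = 0.95) {
  if (!term %in% names(fit$coefficients))
    stop("no such coefficient: ", term)
  b <- scale * fit$coefficients[[term]]
  se <- scale * sqrt(fit$vcov[term, term])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(hr = exp(b), lo = exp(b - z * se), hi = exp(b + z * se),
       log_hr = b, se = se)
}

#' Decade hazard ratio as the geometric mean of half-decade HRs
#'
#' For a fit with a separate exposure slope in each half-decade band, the
#' decade log HR is `(b1 + b2)/2` with delta-method variance
#' `(v1 + v2 + 2*c12)/4`.
#'
#' @param fit a [fit_cox()] result.
#' @param term1,term2 coefficient names of the exposure slopes in the first
#'   and second half of the decade.
#' @param conf confidence level.
#' @return list: `hr`, `lo`, `hi`, `log_hr`, `var`.
#' @export
decade_hr_geometric <- function(fit, term1, term2, conf = 0.95) {
  for (tm in c(term1, term2))
    if (!tm %in% names(fit$coefficients)) stop("no such coefficient: ", tm)
  b1 <- fit$coefficients[[term1]]; b2 <- fit$coefficients[[term2]]
  v1 <- fit$vcov[term1, term1]; v2 <- fit$vcov[term2, term2]
  c12 <- fit$vcov[term1, term2]
  lg <- (b1 + b2) / 2
  vr <- (v1 + v2 + 2 * c12) / 4
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(hr = exp(lg), lo = exp(lg - z * sqrt(vr)), hi = exp(lg + z * sqrt(vr)),
       log_hr = lg, var = vr)
}

#' Floating absolute risks for exposure groups
#'
#' Attributes a "floated" variance to every exposure group, including the
#' reference, so that each group carries its own CI while any pairwise
#' contrast retains (approximately) its correct variance: the reference is
#' augmented with log HR 0, all pairwise contrast variances
#' `Var(b_k - b_l)` are formed from the fitted covariance, and per-group
#' variances `v_k >= 0` are chosen by non-negative least squares to
#' reproduce them.
#'
#' @param fit a [fit_cox()] result.
#' @param terms coefficient names of the non-reference group effects, in
#'   group order.
#' @param ref_label label for the reference group.
#' @param conf confidence level.
#' @return data.frame (class `bpv_floated`): `group`, `log_hr`, `hr`,
#'   `floated_var`, `lo`, `hi`, with attribute `max_rel_residual` = max over
#'   pairs of `|V_kl - (v_k + v_l)|` divided by the mean pairwise variance.
#' @export
floated_absolute_risks <- function(fit, terms, ref_label = "reference",
                                   conf = 0.95) {
  if (length(terms) < 2)
    stop("need >= 3 groups (including the reference); system underdetermined")
  if (!all(terms %in% names(fit$coefficients)))
    stop("missing coefficients: ",
         paste(setdiff(terms, names(fit$coefficients)), collapse = ", "))
  K <- length(terms) + 1
  beta <- c(0, unname(fit$coefficients[terms]))
  V <- matrix(0, K, K)
  V[-1, -1] <- fit$vcov[terms, terms]

  pairs <- utils::combn(K, 2)
  npair <- ncol(pairs)
  A <- matrix(0, npair, K)
  y <- numeric(npair)
  for (p in seq_len(npair)) {
    k <- pairs[1, p]; l <- pairs[2, p]
    A[p, c(k, l)] <- 1
    y[p] <- V[k, k] + V[l, l] - 2 * V[k, l]
  }
  v <- pracma::lsqnonneg(A, y)$x
  resid <- A %*% v - y
  max_rel <- max(abs(resid)) / mean(y)

  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(group = c(ref_label, terms), log_hr = beta,
                    hr = exp(beta), floated_var = v,
                    lo = exp(beta - z * sqrt(v)), hi = exp(beta + z * sqrt(v)),
                    stringsAsFactors = FALSE)
  attr(out, "max_rel_residual") <- max_rel
  class(out) <- c("bpv_floated", "data.frame")
  out
}

#' Restricted (natural) cubic spline basis
#'
#' Truncated-power construction: for knots `t_1 < ... < t_k` the basis is the
#' linear term plus `k - 2` nonlinear terms
#' `[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'   + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2`,
#' which is linear beyond the boundary knots (so extrapolation never errors).
#'
#' @param x numeric vector.
#' @param knots strictly increasing knot vector (>= 3 knots). When `NULL`,
#'   `n_knots` quantiles of `x` are used (10/50/90th percentiles for 3).
#' @param n_knots number of knots when `knots` is `NULL`.
#' @return matrix with columns `lin`, `nl1`, ... and attribute `knots`.
#' @export
rcs_basis <- function(x, knots = NULL, n_knots = 3) {
  if (is.null(knots)) {
    probs <- if (n_knots == 3) c(0.10, 0.50, 0.90)
             else seq(0.05, 0.95, length.out = n_knots)
    knots <- unname(stats::quantile(x, probs, na.rm = TRUE))
  }
  if (length(knots) < 3) stop("need at least 3 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  pp <- function(u) pmax(u, 0)^3
  nl <- sapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (pp(x - tj) - pp(x - tk1) * (tk - tj) / (tk - tk1) +
       pp(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
  })
  out <- cbind(lin = x, matrix(nl, ncol = k - 2,
                               dimnames = list(NULL, paste0("nl", seq_len(k - 2)))))
  attr(out, "knots") <- knots
  out
}

#' Per-5 hazard ratios within subgroups
#'
#' Refits the Cox model within each level of each stratifier (with the
#' stratifier removed from the covariate list) and tabulates the per-5
#' exposure HR, producing a forest-plot-ready long table.
#'
#' @param episodes episode data.frame (see [lexis_split()]).
#' @param term exposure coefficient name (linear, per mm Hg).
#' @param subgroup_vars character vector of stratifier column names (each
#'   coercible to a factor).
#' @param covariates model terms for the pooled specification.
#' @param ties,conf passed to [fit_cox()] / [per5_continuous_hr()].
#' @return data.frame: `subgroup`, `level`, `n_events`, `hr`, `lo`, `hi`.
#'   Strata with no events are skipped with a warning.
#' @export
run_subgroup_analyses <- function(episodes, term = "usual_sd",
                                  subgroup_vars, covariates,
                                  ties = "efron", conf = 0.95) {
  rows <- list()
  for (sv in subgroup_vars) {
    x <- episodes[[sv]]
    if (is.null(x)) stop("no such column: ", sv)
    lv <- if (is.factor(x)) levels(droplevels(factor(x))) else sort(unique(x))
    covs <- setdiff(covariates, sv)
    for (l in lv) {
      sub <- episodes[x == l & !is.na(x), , drop = FALSE]
      if (nrow(sub) == 0 || sum(sub$event) == 0) {
        warning(sprintf("skipping empty stratum %s = %s", sv, l))
        next
      }
      keep <- vapply(covs, function(v) {
        if (grepl("[:*()]", v)) return(TRUE)
        length(unique(sub[[v]][!is.na(sub[[v]])])) >= 2
      }, logical(1))
      f <- fit_cox(sub, covs[keep], ties = ties)
      h <- per5_continuous_hr(f, term = term, conf = conf)
      rows[[length(rows) + 1]] <-
        data.frame(subgroup = sv, level = as.character(l),
                   n_events = f$n_events, hr = h$hr, lo = h$lo, hi = h$hi,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
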
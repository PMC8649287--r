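#' Draw subject-level ground truth
#'
#' Samples, for each subject, the true usual SBP `alpha_i` and slope `beta_i`
#' (bivariate normal), the true within-subject residual SD `sigma_i`
#' (log-normal, parameterised by its natural-scale mean and SD), and the
#' baseline covariates (age, sex, smoking, BMI, HbA1c, LDL-C, creatinine and
#' derived eGFR, Charlson index, drug-use flags). Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()] object.
#' @return a data.frame with one row per subject (class `bpv_truth`).
#' @export
draw_subject_truth <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_subjects

  # (alpha_i, beta_i) bivariate normal
  rho <- config$intercept_slope_corr
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  alpha <- config$mean_usual_sbp + config$sd_usual_sbp * z1
  beta <- config$slope_mean + config$slope_sd * z2

  # sigma_i log-normal matched to natural-scale mean/SD
  if (config$sd_usual_var > 0) {
    cv2 <- (config$sd_usual_var / config$mean_usual_var)^2
    omega2 <- log1p(cv2)
    theta <- log(config$mean_usual_var) - omega2 / 2
    sigma <- exp(stats::rnorm(n, theta, sqrt(omega2)))
  } else {
    sigma <- rep(config$mean_usual_var, n)
  }

  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  male <- stats::rbinom(n, 1, config$male_fraction)
  smoking <- stats::rbinom(n, 1, 0.103)
  bmi <- stats::rnorm(n, 25.6, 4.9)
  hba1c <- stats::rnorm(n, 7.4, 1.4)
  ldl_c <- stats::rnorm(n, 3.2, 1.1)
  dbp <- stats::rnorm(n, 75.3, 10.2)
  creatinine <- exp(stats::rnorm(n, log(75), 0.25))
  egfr <- compute_egfr(creatinine, age, female = male == 0)
  charlson <- pmax(0L, as.integer(round(stats::rnorm(n, 3.0, 1.3))))

  drugs <- data.frame(
    oad = stats::rbinom(n, 1, 0.81),
    insulin = stats::rbinom(n, 1, 0.01),
    acei_arb = stats::rbinom(n, 1, 0.305),
    beta_blocker = stats::rbinom(n, 1, 0.298),
    ccb = stats::rbinom(n, 1, 0.384),
    diuretic = stats::rbinom(n, 1, 0.138),
    other_antihtn = stats::rbinom(n, 1, 0.108),
    lipid_lowering = stats::rbinom(n, 1, 0.098)
  )

  out <- data.frame(
    subject_id = seq_len(n),
    alpha_i = alpha, beta_i = beta, sigma_i = sigma,
    age = age, male = male, smoking = smoking,
    bmi = bmi, hba1c = hba1c, ldl_c = ldl_c, dbp = dbp,
    creatinine = creatinine, egfr = egfr, charlson = charlson,
    drugs
  )
  class(out) <- c("bpv_truth", "data.frame")
  out
}

# truncated normal via inverse-CDF (vectorised, deterministic under seed)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Estimated glomerular filtration rate (recalibrated MDRD)
#'
#' Abbreviated MDRD formula with the Chinese-population recalibration factor
#' 1.233: `186 * (creatinine_mg_dl)^-1.154 * age^-0.203 * (0.742 if female)
#' * 1.233`, with creatinine converted from umol/L by the factor 0.011.
#'
#' @param creatinine serum creatinine in umol/L (positive).
#' @param age age in years (positive).
#' @param female logical flag (vectorised).
#' @return eGFR in mL/min per 1.73 m^2.
#' @export
compute_egfr <- function(creatinine, age, female) {
  if (any(creatinine <= 0)) stop("creatinine must be positive")
  if (any(age <= 0)) stop("age must be positive")
  186 * (creatinine * 0.011)^(-1.154) * age^(-0.203) *
    ifelse(female, 0.742, 1) * 1.233
}

#' Simulate longitudinal SBP series
#'
#' Generates readings `y_ij = alpha_i + beta_i * t_ij + e_ij`,
#' `e_ij ~ N(0, sigma_i^2)`, on the configured visit schedule. The first
#' scheduled visit is always observed; each later visit is retained
#' independently with `retention_prob`. Subjects whose retained visit count
#' falls below `min_readings` have their retention pattern redrawn, so the
#' returned cohort consists of subjects with at least `min_readings` readings.
#'
#' @param truths output of [draw_subject_truth()].
#' @param config the matching [cohort_config()].
#' @return data.frame with columns `subject_id`, `t_years`, `sbp`.
#' @export
simulate_bp_series <- function(truths, config) {
  validate_config(config)
  if (nrow(truths) == 0) stop("truths is empty")
  if (length(config$visit_schedule_months) == 0) stop("empty visit schedule")
  set.seed(config$seed + 1L)

  n <- nrow(truths)
  tt <- config$visit_schedule_months / 12
  v <- length(tt)
  keep <- matrix(TRUE, n, v)
  if (v > 1) {
    keep[, -1] <- stats::runif(n * (v - 1)) < config$retention_prob
    bad <- which(rowSums(keep) < config$min_readings)
    tries <- 0
    while (length(bad) > 0 && tries < 10000) {
      keep[bad, -1] <- stats::runif(length(bad) * (v - 1)) < config$retention_prob
      bad <- bad[rowSums(keep[bad, , drop = FALSE]) < config$min_readings]
      tries <- tries + 1
    }
    if (length(bad) > 0)
      stop("could not reach min_readings for some subjects; raise retention_prob")
  }

  idx <- which(t(keep))  # row-major: subject 1's visits first
  subj <- rep(seq_len(n), times = rowSums(keep))
  tvals <- tt[((idx - 1) %% v) + 1]
  mu <- truths$alpha_i[subj] + truths$beta_i[subj] * tvals
  y <- mu + stats::rnorm(length(subj), 0, truths$sigma_i[subj])
  data.frame(subject_id = truths$subject_id[subj], t_years = tvals, sbp = y)
}

#' Simulate proportional-hazards outcomes
#'
#' Event times are exponential with subject-specific rate
#' `lambda_0 * exp(eta_i)`, where the linear predictor is
#' `b_sd * (sigma_i - mean_usual_var)/5 + sum(coef * centred covariate)` and
#' `b_sd` itself may vary linearly with age (see `sd_hr_age_interaction` in
#' [cohort_config()]), so the generator's per-5 log hazard ratio is exactly
#' the Cox estimand. Administrative censoring at
#' `admin_censor_years - U(0, entry_spread_years)` emulates staggered entry.
#' Events are labelled CVD with probability `cvd_fraction`, otherwise
#' non-CVD death.
#'
#' @param truths output of [draw_subject_truth()].
#' @param config the matching [cohort_config()].
#' @return `truths` with columns `censor_time`, `time_years`, `event`,
#'   `cause` (`"cvd"`, `"death"` or `NA` when censored) appended.
#' @export
simulate_outcomes <- function(truths, config) {
  validate_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(truths)

  b5 <- config$log_hr_per_5mmhg_sd +
    config$sd_hr_age_interaction * (truths$age - 65) / 10
  eta <- b5 * (truths$sigma_i - config$mean_usual_var) / 5
  cf <- config$other_hazard_coefs
  centres <- c(age = config$age_mean, male = 0, usual_sbp = config$mean_usual_sbp,
               smoking = 0, charlson = 3, bmi = 25.6, hba1c = 7.4, ldl_c = 3.2)
  cols <- c(age = "age", male = "male", usual_sbp = "alpha_i",
            smoking = "smoking", charlson = "charlson", bmi = "bmi",
            hba1c = "hba1c", ldl_c = "ldl_c")
  for (nm in names(cf)) {
    if (!nm %in% names(cols)) stop("unknown hazard covariate: ", nm)
    ctr <- if (nm %in% names(centres)) centres[[nm]] else 0
    eta <- eta + cf[[nm]] * (truths[[cols[[nm]]]] - ctr)
  }

  lambda <- config$baseline_hazard_rate * exp(eta)
  t_event <- stats::rexp(n, rate = lambda)
  censor <- config$admin_censor_years -
    stats::runif(n, 0, config$entry_spread_years)
  event <- as.integer(t_event <= censor)
  time <- pmin(t_event, censor)
  cause <- ifelse(event == 1,
                  ifelse(stats::runif(n) < config$cvd_fraction, "cvd", "death"),
                  NA_character_)

  truths$censor_time <- censor
  truths$event_time <- t_event
  truths$time_years <- time
  truths$event <- event
  truths$cause <- cause
  truths
}

#' Long-format outcome table
#'
#' Expands simulated outcomes into one row per subject and outcome type
#' (`composite`, `cvd`, `death`), with death censoring the non-fatal outcome
#' at the event time.
#'
#' @param truths output of [simulate_outcomes()].
#' @return data.frame `subject_id`, `outcome`, `time_years`, `event`.
#' @export
make_outcome_table <- function(truths) {
  stopifnot(all(c("time_years", "event", "cause") %in% names(truths)))
  one <- function(outc, ev) data.frame(subject_id = truths$subject_id,
                                       outcome = outc,
                                       time_years = truths$time_years,
                                       event = as.integer(ev))
  rbind(
    one("composite", truths$event == 1),
    one("cvd", truths$event == 1 & truths$cause %in% "cvd"),
    one("death", truths$event == 1 & truths$cause %in% "death")
  )
}

#' Inject missingness into baseline covariates
#'
#' Deletes cells of the named columns at the requested rates, either
#' completely at random (`"mcar"`) or with probability depending on age
#' through a logistic model (`"mar_age"`), whose intercept is solved so the
#' expected per-column missingness equals the requested rate.
#'
#' @param table a baseline data.frame containing an `age` column when
#'   `mechanism = "mar_age"`.
#' @param rates named vector of missingness proportions in \[0, 1\].
#' @param mechanism `"mcar"` or `"mar_age"`.
#' @param mar_age_slope log-odds of missingness per SD of age.
#' @param seed optional integer; when supplied the deletion is deterministic.
#' @return `table` with `NA`s injected.
#' @export
inject_missing_covariates <- function(table, rates,
                                      mechanism = c("mcar", "mar_age"),
                                      mar_age_slope = 1, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  for (nm in names(rates)) {
    if (!nm %in% names(table)) stop("no such column: ", nm)
    r <- rates[[nm]]
    if (r == 0) next
    n <- nrow(table)
    if (mechanism == "mcar") {
      p <- rep(r, n)
    } else {
      zage <- as.numeric(scale(table$age))
      f <- function(a) mean(stats::plogis(a + mar_age_slope * zage)) - r
      a <- stats::uniroot(f, c(-30, 30))$root
      p <- stats::plogis(a + mar_age_slope * zage)
    }
    table[[nm]][stats::runif(n) < p] <- NA
  }
  table
}

#' Simulate a complete synthetic cohort
#'
#' Runs [draw_subject_truth()], [simulate_bp_series()], [simulate_outcomes()]
#' and [inject_missing_covariates()] and returns the pieces the analysis
#' pipeline consumes, including the ground truth for recovery testing.
#'
#' @param config a [cohort_config()].
#' @return list with elements `truth` (complete, no missingness),
#'   `longitudinal` (readings), `baseline` (covariate table with injected
#'   missingness; no truth columns), `outcomes` (long outcome table) and
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  truth <- draw_subject_truth(config)
  long <- simulate_bp_series(truth, config)
  truth <- simulate_outcomes(truth, config)
  baseline <- truth[, c("subject_id", "age", "male", "smoking", "bmi",
                        "hba1c", "ldl_c", "dbp", "creatinine", "egfr",
                        "charlson", "oad", "insulin", "acei_arb",
                        "beta_blocker", "ccb", "diuretic", "other_antihtn",
                        "lipid_lowering")]
  baseline <- inject_missing_covariates(
    baseline, config$covariate_missing_rates,
    mechanism = config$missing_mechanism,
    mar_age_slope = config$mar_age_slope,
    seed = config$seed + 3L)
  list(truth = truth, longitudinal = long, baseline = baseline,
       outcomes = make_outcome_table(truth), config = config)
}

#' Write a simulated cohort to delimited files
#'
#' Writes `longitudinal.csv`, `baseline.csv`, `outcomes.csv` and `config.yaml`
#' into `dir`; floats carry 6 significant digits.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  }
  wr(cohort$longitudinal, "longitudinal.csv")
  wr(cohort$baseline, "baseline.csv")
  wr(cohort$outcomes, "outcomes.csv")
  write_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
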
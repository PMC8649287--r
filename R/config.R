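#' Synthetic cohort generator configuration
#'
#' Builds the configuration object consumed by [draw_subject_truth()],
#' [simulate_bp_series()], [simulate_outcomes()] and [simulate_cohort()].
#' Defaults emulate a primary-care type-2 diabetes cohort aged 45-84 with
#' quarterly SBP readings over two years (up to 9 readings), a subject-level
#' usual SBP of 137.1 (SD 10.7) mm Hg, a subject-level residual SD of 12.7
#' (SD 2.3) mm Hg, and proportional-hazards outcomes whose log hazard is
#' linear in the subject's true within-subject SD.
#'
#' @param n_subjects number of subjects to generate.
#' @param visit_schedule_months scheduled visit times in months from the first
#'   reading; the first visit is always observed.
#' @param retention_prob probability that each scheduled visit after the first
#'   yields a reading. The default 0.2678 is calibrated so that, together with
#'   the `min_readings` rejection step, the expected number of readings per
#'   retained subject is 4.5.
#' @param min_readings minimum readings per subject; subjects below this have
#'   their retention pattern redrawn.
#' @param mean_usual_sbp,sd_usual_sbp population mean and SD of the true
#'   subject-level usual SBP `alpha_i` (mm Hg).
#' @param mean_usual_var,sd_usual_var population mean and SD, on the natural
#'   scale, of the true within-subject residual SD `sigma_i` (mm Hg); the
#'   population law is log-normal.
#' @param slope_mean,slope_sd population mean and SD of the true subject-level
#'   SBP slope `beta_i` (mm Hg per year).
#' @param intercept_slope_corr correlation between `alpha_i` and `beta_i`,
#'   in (-1, 1).
#' @param age_range inclusive baseline age range (years).
#' @param age_mean,age_sd mean/SD of the (truncated normal) baseline age.
#' @param male_fraction proportion of male subjects.
#' @param log_hr_per_5mmhg_sd true log hazard ratio per 5 mm Hg of `sigma_i`.
#' @param sd_hr_age_interaction modifier of the per-5 log hazard ratio per
#'   decade of age above 65 (negative values make the association stronger at
#'   younger ages); 0 disables the interaction.
#' @param other_hazard_coefs named vector of log hazard ratios for centred
#'   baseline covariates entering the event hazard.
#' @param baseline_hazard_rate baseline event hazard (events per person-year)
#'   at covariate reference values.
#' @param admin_censor_years administrative censoring horizon (years).
#' @param entry_spread_years staggered-entry width: each subject's
#'   administrative censoring time is `admin_censor_years - U(0, entry_spread_years)`,
#'   so that the reverse Kaplan-Meier median follow-up is about 9.7 years at
#'   the defaults.
#' @param cvd_fraction probability that a generated event is labelled a CVD
#'   event rather than a non-CVD death.
#' @param covariate_missing_rates named vector of per-column missingness
#'   proportions applied by [inject_missing_covariates()].
#' @param missing_mechanism `"mcar"` (default) or `"mar_age"`.
#' @param mar_age_slope log-odds of missingness per SD of age under
#'   `"mar_age"`.
#' @param seed integer seed; all generator functions are deterministic given
#'   the config.
#'
#' @return an object of class `bpv_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 2000,
                          visit_schedule_months = seq(0, 24, by = 3),
                          retention_prob = 0.2678,
                          min_readings = 4,
                          mean_usual_sbp = 137.1, sd_usual_sbp = 10.7,
                          mean_usual_var = 12.7, sd_usual_var = 2.3,
                          slope_mean = 0.5, slope_sd = 2,
                          intercept_slope_corr = 0,
                          age_range = c(45, 84), age_mean = 63.9, age_sd = 10,
                          male_fraction = 0.452,
                          log_hr_per_5mmhg_sd = log(1.30),
                          sd_hr_age_interaction = 0,
                          other_hazard_coefs = c(age = 0.07, male = 0.25,
                                                 usual_sbp = 0.015,
                                                 smoking = 0.30,
                                                 charlson = 0.15),
                          baseline_hazard_rate = 0.03,
                          admin_censor_years = 10,
                          entry_spread_years = 0.6,
                          cvd_fraction = 0.60,
                          covariate_missing_rates = c(bmi = 0.354,
                                                      ldl_c = 0.364,
                                                      egfr = 0.229,
                                                      hba1c = 0.10,
                                                      smoking = 0.05),
                          missing_mechanism = c("mcar", "mar_age"),
                          mar_age_slope = 1,
                          seed = 20080101L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    visit_schedule_months = as.numeric(visit_schedule_months),
    retention_prob = retention_prob,
    min_readings = as.integer(min_readings),
    mean_usual_sbp = mean_usual_sbp, sd_usual_sbp = sd_usual_sbp,
    mean_usual_var = mean_usual_var, sd_usual_var = sd_usual_var,
    slope_mean = slope_mean, slope_sd = slope_sd,
    intercept_slope_corr = intercept_slope_corr,
    age_range = as.numeric(age_range), age_mean = age_mean, age_sd = age_sd,
    male_fraction = male_fraction,
    log_hr_per_5mmhg_sd = log_hr_per_5mmhg_sd,
    sd_hr_age_interaction = sd_hr_age_interaction,
    other_hazard_coefs = other_hazard_coefs,
    baseline_hazard_rate = baseline_hazard_rate,
    admin_censor_years = admin_censor_years,
    entry_spread_years = entry_spread_years,
    cvd_fraction = cvd_fraction,
    covariate_missing_rates = covariate_missing_rates,
    missing_mechanism = missing_mechanism,
    mar_age_slope = mar_age_slope,
    seed = as.integer(seed)
  )
  class(cfg) <- "bpv_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "bpv_config"))
  with(cfg, {
    if (n_subjects < 1) stop("n_subjects must be positive")
    if (length(visit_schedule_months) < 1) stop("visit schedule is empty")
    if (retention_prob < 0 || retention_prob > 1)
      stop("retention_prob must lie in [0, 1]")
    if (male_fraction < 0 || male_fraction > 1)
      stop("male_fraction must lie in [0, 1]")
    if (cvd_fraction < 0 || cvd_fraction > 1)
      stop("cvd_fraction must lie in [0, 1]")
    if (sd_usual_sbp <= 0) stop("sd_usual_sbp must be > 0")
    if (sd_usual_var < 0) stop("sd_usual_var must be >= 0")
    if (slope_sd < 0) stop("slope_sd must be >= 0")
    if (age_sd <= 0) stop("age_sd must be > 0")
    if (abs(intercept_slope_corr) >= 1)
      stop("intercept_slope_corr must lie in (-1, 1)")
    if (min_readings < 2) stop("min_readings must be >= 2")
    if (min_readings > length(visit_schedule_months))
      stop("min_readings exceeds the number of scheduled visits")
    if (baseline_hazard_rate <= 0) stop("baseline_hazard_rate must be > 0")
    if (admin_censor_years <= 0) stop("admin_censor_years must be > 0")
    if (entry_spread_years < 0) stop("entry_spread_years must be >= 0")
    if (any(covariate_missing_rates < 0 | covariate_missing_rates > 1))
      stop("covariate_missing_rates must lie in [0, 1]")
    if (!all(is.finite(other_hazard_coefs)))
      stop("other_hazard_coefs must be finite")
  })
  invisible(cfg)
}

#' Read or write a generator configuration as YAML
#'
#' @param cfg a `bpv_config` object.
#' @param path file path.
#' @return `read_config()` returns a `bpv_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  x <- unclass(cfg)
  x$other_hazard_coefs <- as.list(x$other_hazard_coefs)
  x$covariate_missing_rates <- as.list(x$covariate_missing_rates)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$other_hazard_coefs <- unlist(x$other_hazard_coefs)
  x$covariate_missing_rates <- unlist(x$covariate_missing_rates)
  do.call(cohort_config, x)
}
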
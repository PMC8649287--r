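# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# cohort of 200 subjects with the full 9-reading schedule plus model fit
fixture_fit9 <- function() fixture("fit9", function() {
  cfg <- cohort_config(n_subjects = 200, retention_prob = 1, seed = 301)
  coh <- simulate_cohort(cfg)
  fit <- suppressWarnings(
    fit_usual_bp(coh$longitudinal,
                 mcmc = mcmc_control(chains = 2, iterations = 900,
                                     burn_in = 300, seed = 301,
                                     on_nonconvergence = "warn")))
  list(cohort = coh, fit = fit,
       naive = naive_subject_stats(coh$longitudinal))
})

# cohort of 200 subjects with exactly 4 readings each plus model fit
fixture_fit4 <- function() fixture("fit4", function() {
  cfg <- cohort_config(n_subjects = 200, visit_schedule_months = c(0, 3, 6, 9),
                       retention_prob = 1, seed = 302)
  coh <- simulate_cohort(cfg)
  fit <- suppressWarnings(
    fit_usual_bp(coh$longitudinal,
                 mcmc = mcmc_control(chains = 2, iterations = 900,
                                     burn_in = 300, seed = 302,
                                     on_nonconvergence = "warn")))
  list(cohort = coh, fit = fit,
       naive = naive_subject_stats(coh$longitudinal))
})

# episode set with a strong positive variability effect for survival tests
# (true sigma_i as the exposure: isolates the survival machinery from the
# measurement model; the strong effect makes group ordering testable)
fixture_episodes <- function() fixture("episodes", function() {
  cfg <- cohort_config(n_subjects = 4000, log_hr_per_5mmhg_sd = log(1.8),
                       seed = 303)
  coh <- simulate_cohort(cfg)
  d <- coh$truth
  d <- d[d$time_years > 0, ]
  d$usual_sd <- d$sigma_i
  d$usual_sbp <- d$alpha_i
  lexis_split(d)
})

# 6-subject untied toy data in counting-process form
toy_cox_data <- function() {
  data.frame(tstart = 0, tstop = 1:6, event = c(1, 0, 1, 1, 0, 1),
             x = c(1, 1, 0, 1, 0, 0))
}

# tied-time toy data (three events share a time, asymmetric in x, so the
# Efron and Breslow approximations genuinely differ)
toy_cox_tied <- function() {
  data.frame(tstart = 0, tstop = c(1, 1, 1, 2, 3, 4, 5, 6),
             event = c(1, 1, 1, 0, 1, 1, 0, 0),
             x = c(1, 1, 0, 1, 0, 1, 0, 0))
}
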
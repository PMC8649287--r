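test_that("subjects with too few readings are excluded with a report", {
  rec <- data.frame(subject_id = rep(1:3, c(3, 4, 9)),
                    t_years = c(seq(0, .5, .25), seq(0, .75, .25), seq(0, 2, .25)),
                    sbp = 130)
  out <- filter_min_records(rec, 4)
  expect_equal(sort(unique(out$subject_id)), c(2, 3))
  expect_equal(attr(out, "n_excluded"), 1L)
  expect_equal(attr(out, "excluded_ids"), "1")
  # relaxing the cutoff strictly enlarges the cohort
  out2 <- filter_min_records(rec, 2)
  expect_true(all(unique(out$subject_id) %in% unique(out2$subject_id)))
  expect_gt(length(unique(out2$subject_id)), length(unique(out$subject_id)))
  # identity when everyone qualifies
  full <- rec[rec$subject_id == 3, ]
  expect_equal(filter_min_records(full, 4)$sbp, full$sbp)
  expect_error(filter_min_records(rec, 1), "k must be")
})

test_that("naive per-subject statistics match a two-pass oracle", {
  set.seed(61)
  rec <- data.frame(subject_id = rep(1:20, each = 6),
                    t_years = rep(seq(0, 1.25, 0.25), 20),
                    sbp = rnorm(120, 135, 12))
  ns <- naive_subject_stats(rec)
  for (i in c(1, 7, 20)) {
    sub <- rec[rec$subject_id == i, ]
    expect_equal(ns$naive_sd[ns$subject_id == i],
                 oracle_two_pass_sd(sub$t_years, sub$sbp), tolerance = 1e-10)
    expect_equal(ns$mean_sbp[ns$subject_id == i], mean(sub$sbp))
  }
})

test_that("degenerate reading patterns give zero SD", {
  rec <- data.frame(subject_id = rep(1:2, each = 3),
                    t_years = rep(c(0, 0.5, 1), 2),
                    sbp = c(128, 128, 128, 120, 130, 140))
  ns <- naive_subject_stats(rec)
  expect_equal(ns$naive_sd[1], 0)          # constant readings
  expect_equal(ns$naive_sd[2], 0)          # collinear readings, detrended
  expect_equal(naive_subject_stats(rec, detrend = FALSE)$naive_sd[1], 0)
  expect_error(naive_subject_stats(data.frame(subject_id = 1, t_years = 0,
                                              sbp = 120)), "<2")
})

test_that("hierarchical fit beats naive SDs in RMSE and correlation", {
  f9 <- fixture_fit9()
  s <- merge(f9$fit$subjects, f9$cohort$truth[, c("subject_id", "sigma_i")],
             by = "subject_id")
  s <- merge(s, f9$naive[, c("subject_id", "naive_sd")], by = "subject_id")
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(s$usual_sd, s$sigma_i), rmse(s$naive_sd, s$sigma_i))

  f4 <- fixture_fit4()
  s4 <- merge(f4$fit$subjects, f4$cohort$truth[, c("subject_id", "sigma_i")],
              by = "subject_id")
  s4 <- merge(s4, f4$naive[, c("subject_id", "naive_sd")], by = "subject_id")
  expect_lt(rmse(s4$usual_sd, s4$sigma_i), rmse(s4$naive_sd, s4$sigma_i))
  expect_gt(cor(s4$usual_sd, s4$sigma_i), cor(s4$naive_sd, s4$sigma_i))
})

test_that("posterior SDs shrink toward the population centre", {
  f9 <- fixture_fit9()
  s <- merge(f9$fit$subjects, f9$naive[, c("subject_id", "naive_sd")],
             by = "subject_id")
  centre <- exp(f9$fit$hyper$theta + f9$fit$hyper$omega^2 / 2)
  # compare against the c4-debiased sample SD (the raw SD underestimates
  # sigma), for subjects whose naive SD sits clearly away from the centre
  # so the shrinkage direction is well defined
  ns <- s$naive_sd / c4_const(9)
  far <- abs(ns - centre) > 1
  between <- (s$usual_sd >= pmin(ns, centre) - 1e-9) &
    (s$usual_sd <= pmax(ns, centre) + 1e-9)
  expect_gt(sum(far), 100)
  expect_gte(mean(between[far]), 0.95)
})

test_that("a homogeneous-variance cohort concentrates the usual SDs", {
  cfg <- cohort_config(n_subjects = 150, retention_prob = 1,
                       sd_usual_var = 0, seed = 304)
  coh <- simulate_cohort(cfg)
  fit <- suppressWarnings(
    fit_usual_bp(coh$longitudinal,
                 mcmc = mcmc_control(chains = 2, iterations = 900,
                                     burn_in = 300, seed = 304,
                                     on_nonconvergence = "warn")))
  naive <- naive_subject_stats(coh$longitudinal)
  expect_lt(sd(fit$subjects$usual_sd), 0.25 * sd(naive$naive_sd))
  expect_lt(abs(mean(fit$subjects$usual_sd) - 12.7), 1)
})

test_that("hyperparameters recover the generating values", {
  cfg <- cohort_config(n_subjects = 1000, retention_prob = 1, seed = 305)
  coh <- simulate_cohort(cfg)
  fit <- suppressWarnings(
    fit_usual_bp(coh$longitudinal,
                 mcmc = mcmc_control(chains = 2, iterations = 1500,
                                     burn_in = 500, seed = 305,
                                     on_nonconvergence = "warn")))
  # generating values on the log scale
  cv2 <- (2.3 / 12.7)^2
  omega_true <- sqrt(log(1 + cv2))
  theta_true <- log(12.7) - log(1 + cv2) / 2
  d <- fit$draws
  post_sd <- function(p) sd(as.numeric(d[, , p]))
  expect_lt(abs(fit$hyper$theta - theta_true), 3 * post_sd("theta"))
  expect_lt(abs(fit$hyper$omega - omega_true), 3 * post_sd("omega"))
  expect_lt(abs(fit$hyper$mu[1] - 137.1), 3 * post_sd("mu1"))
  # diagnostics exist for every hyperparameter
  expect_setequal(fit$diagnostics$parameter,
                  c("mu1", "mu2", "Sigma11", "Sigma12", "Sigma22",
                    "theta", "omega"))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$ess > 0))
})

test_that("MCMC summaries are reproducible under a fixed seed", {
  cfg <- cohort_config(n_subjects = 60, retention_prob = 1, seed = 306)
  coh <- simulate_cohort(cfg)
  mc <- mcmc_control(chains = 2, iterations = 400, burn_in = 150, seed = 7,
                     on_nonconvergence = "warn")
  f1 <- suppressWarnings(fit_usual_bp(coh$longitudinal, mcmc = mc))
  f2 <- suppressWarnings(fit_usual_bp(coh$longitudinal, mcmc = mc))
  expect_identical(f1$subjects, f2$subjects)
  expect_identical(f1$draws, f2$draws)
})

test_that("degenerate designs are rejected", {
  rec <- data.frame(subject_id = rep(1, 4), t_years = rep(0.5, 4),
                    sbp = c(120, 125, 130, 128))
  expect_error(fit_usual_bp(rec), "degenerate|same time")
  expect_error(fit_usual_bp(data.frame(subject_id = 1, t_years = 0, sbp = 1)),
               ">= 2 readings")
})

test_that("window split pairs first- and second-year estimates", {
  cfg <- cohort_config(n_subjects = 400, seed = 307)
  coh <- simulate_cohort(cfg)
  win <- window_variability(coh$longitudinal)
  expect_true(all(win$n1 >= 2 & win$n2 >= 2))
  expect_true(all(is.finite(win$sd1) & is.finite(win$sd2)))
  # every paired subject really has enough readings on each side
  long <- coh$longitudinal
  for (id in win$subject_id[1:5]) {
    sub <- long[long$subject_id == id, ]
    expect_gte(sum(sub$t_years <= 1), 2)
    expect_gte(sum(sub$t_years > 1), 2)
  }
})

test_that("the dilution ratio matches its least-squares definition", {
  # identical windows: no attenuation
  x <- c(9, 11, 12.5, 14, 16, 13)
  r <- rosner_dilution_ratio(x, x)
  expect_equal(r$slope, 1)
  expect_equal(r$lambda, 1)
  expect_equal(rosner_correct(0.3, r), 0.3)
  # constructed pairs with exact slope 0.25 -> lambda 4
  set.seed(62)
  f <- rnorm(200, 12, 3)
  s <- 5 + 0.25 * f
  r2 <- rosner_dilution_ratio(f, s)
  expect_equal(r2$slope, 0.25, tolerance = 1e-12)
  expect_equal(r2$lambda, 4, tolerance = 1e-12)
  expect_error(rosner_dilution_ratio(rep(12, 10), rnorm(10)), "zero variance")
})

test_that("shrinkage-corrected exposures reduce attenuation in the hazard model", {
  # positive true effect: naive-SD HR attenuated relative to usual-SD HR
  f9 <- fixture_fit9()
  d <- f9$cohort$truth
  s <- merge(f9$fit$subjects, f9$naive[, c("subject_id", "naive_sd")],
             by = "subject_id")
  s$subject_id <- as.integer(s$subject_id)
  d <- merge(d, s[, c("subject_id", "usual_sd", "naive_sd")], by = "subject_id")
  d <- d[d$time_years > 0, ]
  fu <- survival::coxph(survival::Surv(time_years, event) ~ usual_sd, data = d)
  fn <- survival::coxph(survival::Surv(time_years, event) ~ naive_sd, data = d)
  expect_gt(coef(fu)[["usual_sd"]], coef(fn)[["naive_sd"]])
})
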
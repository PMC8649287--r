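test_that("variability groups use the half-open clinical cutpoints", {
  expect_equal(as.character(assign_variability_group(9.0)), "<10")
  expect_equal(as.character(assign_variability_group(10.0)), "10-11.9")
  expect_equal(as.character(assign_variability_group(11.999)), "10-11.9")
  expect_equal(as.character(assign_variability_group(12.0)), "12-13.9")
  expect_equal(as.character(assign_variability_group(14.0)), "14-15.9")
  expect_equal(as.character(assign_variability_group(16.0)), ">=16")
  expect_equal(as.character(assign_variability_group(17.4)), ">=16")
  expect_error(assign_variability_group(0), "positive")
})

test_that("episodes split exactly at attained-age boundaries", {
  d <- data.frame(subject_id = 1, age = 53.2, time_years = 4.0, event = 1)
  ep <- lexis_split(d)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$entry_age, c(53.2, 55))
  expect_equal(ep$exit_age, c(55, 57.2))
  expect_equal(ep$event, c(0L, 1L))
  expect_equal(as.character(ep$age_band), c("45-54", "55-64"))
  expect_equal(as.character(ep$half_decade_band), c("50-54", "55-59"))
  expect_equal(ep$tstart, c(0, 1.8))
  expect_equal(ep$tstop, c(1.8, 4.0))
})

test_that("Lexis expansion conserves person-time and events exactly", {
  set.seed(71)
  n <- 400
  d <- data.frame(subject_id = 1:n, age = runif(n, 45, 84),
                  time_years = rexp(n, 0.15) + 0.01,
                  event = rbinom(n, 1, 0.4))
  ep <- lexis_split(d)
  expect_equal(sum(ep$exit_age - ep$entry_age), sum(d$time_years))
  expect_equal(sum(ep$tstop - ep$tstart), sum(d$time_years))
  expect_equal(sum(ep$event), sum(d$event))
  # episodes of each subject are disjoint and contiguous
  byid <- split(ep, ep$subject_id)
  ok <- vapply(byid, function(e) {
    e <- e[order(e$entry_age), ]
    all(abs(e$entry_age[-1] - e$exit_age[-nrow(e)]) < 1e-12)
  }, logical(1))
  expect_true(all(ok))
  # ages above 84 stay in the top bands
  old <- ep[ep$entry_age >= 85, ]
  if (nrow(old) > 0) {
    expect_true(all(old$age_band == "75-84"))
    expect_true(all(old$half_decade_band == "80-84"))
  }
  expect_error(lexis_split(transform(d, time_years = -1)), "negative")
})

test_that("per-band person-years agree with a day-by-day tally", {
  set.seed(72)
  n <- 500
  d <- data.frame(subject_id = 1:n, age = runif(n, 45, 84),
                  time_years = runif(n, 0.1, 12), event = 0L)
  ep <- lexis_split(d)
  got <- tapply(ep$exit_age - ep$entry_age, ep$age_band, sum, default = 0)
  # brute force: accumulate day midpoints into decade bands
  bands <- c("45-54", "55-64", "65-74", "75-84")
  tally <- setNames(numeric(4), bands)
  for (i in seq_len(n)) {
    days <- seq(0, d$time_years[i], by = 1 / 365)
    if (length(days) < 2) next
    mids <- d$age[i] + (days[-1] + days[-length(days)]) / 2
    b <- pmin(pmax(floor((mids - 45) / 10), 0), 3) + 1
    for (k in 1:4) tally[k] <- tally[k] + sum(b == k) / 365
  }
  for (k in bands)
    expect_lt(abs(got[[k]] - tally[[k]]), n / 365)
})

test_that("label-swapped exposure groups give a zero log hazard ratio", {
  # two groups whose event patterns are exactly exchangeable
  d <- data.frame(tstart = 0, tstop = rep(c(1, 2, 3, 4), 2),
                  event = rep(c(1, 0, 1, 0), 2),
                  x = rep(c(0, 1), each = 4))
  f <- fit_cox(d, "x")
  expect_lt(abs(f$coefficients[["x"]]), 1e-8)
})

test_that("the partial-likelihood maximum matches a grid-search oracle", {
  d <- toy_cox_data()
  f <- fit_cox(d, "x", ties = "efron")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b)
    oracle_cox_loglik(b, d$tstart, d$tstop, d$event, d["x"], "efron"), 0)
  expect_lt(abs(f$coefficients[["x"]] - grid[which.max(ll)]), 1e-4)
  # analytic score at the reported optimum is numerically zero
  g <- oracle_cox_grad(f$coefficients, d$tstart, d$tstop, d$event, d["x"],
                       "efron")
  expect_lt(abs(g), 1e-8)
  # the optimum improves on the null
  expect_gte(f$loglik[2], f$loglik[1])
})

test_that("Efron and Breslow ties each match their own likelihood", {
  d <- toy_cox_tied()
  fe <- fit_cox(d, "x", ties = "efron")
  fb <- fit_cox(d, "x", ties = "breslow")
  expect_false(isTRUE(all.equal(fe$coefficients, fb$coefficients)))
  for (m in c("efron", "breslow")) {
    f <- if (m == "efron") fe else fb
    opt <- optimize(function(b)
      oracle_cox_loglik(b, d$tstart, d$tstop, d$event, d["x"], m),
      c(-4, 4), maximum = TRUE, tol = 1e-10)
    expect_lt(abs(f$coefficients[["x"]] - opt$maximum), 1e-5)
    expect_equal(f$loglik[2],
                 oracle_cox_loglik(f$coefficients, d$tstart, d$tstop,
                                   d$event, d["x"], m))
    g <- oracle_cox_grad(f$coefficients, d$tstart, d$tstop, d$event,
                         d["x"], m)
    expect_lt(abs(g), 1e-8)
  }
  expect_error(fit_cox(transform(toy_cox_data(), x = 1), "x"), "constant")
  expect_error(fit_cox(transform(toy_cox_data(), event = 0), "x"), "no events")
})

test_that("per-5 transformation maps coefficients to hazard ratios", {
  fake <- structure(list(coefficients = c(usual_sd = 0),
                         vcov = matrix(0.01, 1, 1,
                                       dimnames = list("usual_sd", "usual_sd"))),
                    class = "bpv_cox")
  expect_equal(per5_continuous_hr(fake)$hr, 1)
  fake$coefficients <- c(usual_sd = log(1.27) / 5)
  expect_equal(per5_continuous_hr(fake)$hr, 1.27)
  expect_error(per5_continuous_hr(fake, term = "absent"), "no such")
})

test_that("the per-5 HR on true exposure recovers the generator truth", {
  ep <- fixture_episodes()
  f <- fit_cox(ep, c("usual_sd", "usual_sbp", "age", "male", "smoking",
                     "charlson", "age_band"))
  h <- per5_continuous_hr(f)
  expect_lt(abs(h$log_hr - log(1.8)), 4 * h$se)  # generator truth 1.8 per 5
})

test_that("decade HRs combine half-decades by geometric mean with delta variance", {
  mkfit <- function(b, V) structure(list(coefficients = b, vcov = V),
                                    class = "bpv_cox")
  nm <- c("h1", "h2")
  # idempotence: equal halves return the common HR
  V0 <- matrix(c(0.01, 0, 0, 0.04), 2, 2, dimnames = list(nm, nm))
  f <- mkfit(setNames(c(log(1.5), log(1.5)), nm), V0)
  expect_equal(decade_hr_geometric(f, "h1", "h2")$hr, 1.5)
  # worked case: HR halves 1.2 and 1.8 -> sqrt(2.16), Var (v1+v2)/4
  f2 <- mkfit(setNames(c(log(1.2), log(1.8)), nm), V0)
  d2 <- decade_hr_geometric(f2, "h1", "h2")
  expect_equal(d2$hr, sqrt(1.2 * 1.8), tolerance = 1e-12)
  expect_equal(d2$var, 0.0125)
  # perfect anticorrelation collapses the variance to zero
  V1 <- matrix(c(0.02, -0.02, -0.02, 0.02), 2, 2, dimnames = list(nm, nm))
  expect_equal(decade_hr_geometric(mkfit(setNames(c(0.1, 0.3), nm), V1),
                                   "h1", "h2")$var, 0)
})

test_that("the delta-method decade variance matches a parametric bootstrap", {
  nm <- c("h1", "h2")
  V <- matrix(c(0.01, 0.004, 0.004, 0.04), 2, 2, dimnames = list(nm, nm))
  f <- structure(list(coefficients = setNames(c(log(1.2), log(1.8)), nm),
                      vcov = V), class = "bpv_cox")
  d <- decade_hr_geometric(f, "h1", "h2")
  set.seed(73)
  bb <- MASS::mvrnorm(2e5, f$coefficients, V)
  boot_var <- var((bb[, 1] + bb[, 2]) / 2)
  expect_lt(abs(d$var / boot_var - 1), 0.05)
})

test_that("floated variances solve the pairwise-contrast system", {
  nm <- c("g2", "g3")
  # symmetric exact case: independent non-reference groups, equal variance
  v <- 0.03
  f <- structure(list(coefficients = setNames(c(0.2, 0.5), nm),
                      vcov = matrix(c(v, 0, 0, v), 2, 2,
                                    dimnames = list(nm, nm))),
                 class = "bpv_cox")
  fl <- floated_absolute_risks(f, nm)
  expect_equal(fl$floated_var, c(0, v, v), tolerance = 1e-10)
  # correlated toy covariance solves the 3x3 linear system
  f2 <- structure(list(coefficients = setNames(c(0.2, 0.5), nm),
                       vcov = matrix(c(0.02, 0.01, 0.01, 0.03), 2, 2,
                                     dimnames = list(nm, nm))),
                  class = "bpv_cox")
  fl2 <- floated_absolute_risks(f2, nm)
  expect_equal(fl2$floated_var, c(0.01, 0.01, 0.02), tolerance = 1e-10)
  expect_lt(attr(fl2, "max_rel_residual"), 1e-10)
  # reference carries its own CI
  expect_true(all(fl2$lo > 0) && all(fl2$hi > fl2$lo))
  expect_error(floated_absolute_risks(f, "g2"), "underdetermined")
})

test_that("floated variances reproduce pairwise contrasts on a real fit", {
  ep <- fixture_episodes()
  ep$var_group <- assign_variability_group(ep$usual_sd)
  lev <- levels(ep$var_group)
  f <- fit_cox(ep, c("var_group", "usual_sbp", "age", "male", "age_band"))
  fl <- floated_absolute_risks(f, paste0("var_group", lev[-1]),
                               ref_label = lev[1])
  expect_lt(attr(fl, "max_rel_residual"), 0.10)
  # positive generating effect: floated log HRs increase across groups
  expect_true(all(diff(fl$log_hr) > 0))
})

test_that("the restricted cubic spline basis is linear in the tails", {
  kn <- c(10, 12.7, 16)
  x <- c(5, 8, 9.99, 12.7, 20, 30, 40)
  B <- rcs_basis(x, knots = kn)
  expect_equal(B[, "lin"], x)
  # below the first knot the nonlinear column vanishes
  expect_equal(B[x < 10, "nl1"], rep(0, 3))
  # far beyond the last knot: zero second differences (linearity)
  xe <- c(30, 31, 32)
  Be <- rcs_basis(xe, knots = kn)
  expect_lt(abs(diff(diff(Be[, "nl1"]))), 1e-9)
  # value at an interior point matches the truncated-power formula
  expect_equal(as.numeric(B[x == 12.7, "nl1"]),
               oracle_rcs_nl(12.7, 10, 12.7, 16))
  expect_equal(as.numeric(B[x == 20, "nl1"]),
               oracle_rcs_nl(20, 10, 12.7, 16))
  expect_error(rcs_basis(x, knots = c(10, 10, 16)), "increasing")
})

test_that("subgroup analyses respect strata and reduce to the pooled fit", {
  ep <- fixture_episodes()
  covs <- c("usual_sd", "usual_sbp", "age", "male", "age_band")
  ep$one_level <- 1
  tab <- run_subgroup_analyses(ep, subgroup_vars = "one_level",
                               covariates = covs)
  pooled <- per5_continuous_hr(fit_cox(ep, covs))
  expect_equal(tab$hr, pooled$hr, tolerance = 1e-10)
  # sex strata both estimable on a positive-effect cohort
  tab2 <- run_subgroup_analyses(ep, subgroup_vars = "male", covariates = covs)
  expect_equal(nrow(tab2), 2)
  expect_true(all(tab2$hr > 0.8))
})

test_that("a built-in age interaction produces age-graded subgroup HRs", {
  cfg <- cohort_config(n_subjects = 4000, sd_hr_age_interaction = -0.35,
                       seed = 308)
  d <- simulate_outcomes(draw_subject_truth(cfg), cfg)
  d <- d[d$time_years > 0, ]
  d$usual_sd <- d$sigma_i
  d$usual_sbp <- d$alpha_i
  ep <- lexis_split(d)
  ep$age_half <- factor(ifelse(ep$age < 65, "45-64", "65-84"))
  # age_band is left out of the within-stratum fits: inside a coarse age
  # stratum some attained-age bands are nearly empty and their dummies
  # run away (separation)
  tab <- run_subgroup_analyses(ep, subgroup_vars = "age_half",
                               covariates = c("usual_sd", "usual_sbp", "age",
                                              "male"))
  expect_gt(tab$hr[tab$level == "45-64"], tab$hr[tab$level == "65-84"])
})

test_that("null-effect cohorts give null subgroup HRs", {
  cfg <- cohort_config(n_subjects = 3000, log_hr_per_5mmhg_sd = 0, seed = 309)
  d <- simulate_outcomes(draw_subject_truth(cfg), cfg)
  d <- d[d$time_years > 0, ]
  d$usual_sd <- d$sigma_i
  d$usual_sbp <- d$alpha_i
  ep <- lexis_split(d)
  covs <- c("usual_sd", "usual_sbp", "age", "male", "age_band")
  tab <- run_subgroup_analyses(ep, subgroup_vars = "male", covariates = covs)
  for (i in 1:2) {
    se <- (log(tab$hi[i]) - log(tab$hr[i])) / qnorm(0.975)
    expect_lt(abs(log(tab$hr[i])), 3 * se)
  }
})
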
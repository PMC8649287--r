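#!/usr/bin/env Rscript
# Cox models for the composite outcome on attained-age-split episodes, run
# on every imputed table and pooled by Rubin's rules: per-5 mm Hg continuous
# HR (usual SD vs naive SD vs Rosner-corrected single-window SD), the
# five-group model with floating absolute risks, a restricted-cubic-spline
# check of log-linearity, and sex subgroups. Writes hr_table.csv and
# forest.csv.

library(bpvar)

usual <- read.csv("results/usual.csv")
long <- read.csv("results/cohort/longitudinal.csv")
covs <- c("usual_sbp", "age", "male", "smoking", "bmi", "hba1c", "ldl_c",
          "dbp", "egfr", "charlson", "oad", "insulin", "acei_arb",
          "beta_blocker", "ccb", "diuretic", "other_antihtn",
          "lipid_lowering", "age_band")

imps <- lapply(1:5, function(k)
  read.csv(sprintf("results/baseline_imp_%d.csv", k)))
eps <- lapply(imps, function(d) {
  d <- merge(d, usual[, c("subject_id", "naive_sd")], by = "subject_id")
  lexis_split(d)
})

pool5 <- function(term, eps_list, covariates) {
  per <- lapply(eps_list, function(ep) {
    per5_continuous_hr(fit_cox(ep, c(term, covariates)), term = term)
  })
  p <- rubin_pool(vapply(per, `[[`, 0, "log_hr"),
                  vapply(per, `[[`, 0, "se")^2)
  c(hr = exp(p$qbar), lo = exp(p$lo), hi = exp(p$hi))
}

h_usual <- pool5("usual_sd", eps, covs)
h_naive <- pool5("naive_sd", eps, setdiff(covs, "usual_sbp"))
cat(sprintf("per-5 HR, usual SD: %.3f (%.3f-%.3f)\n",
            h_usual[1], h_usual[2], h_usual[3]))
cat(sprintf("per-5 HR, naive SD: %.3f (%.3f-%.3f)  <- attenuated\n",
            h_naive[1], h_naive[2], h_naive[3]))

# Rosner sensitivity route: first-year exposure corrected by 1/slope
win <- window_variability(long)
ros <- rosner_dilution_ratio(win$sd1, win$sd2)
eps_w1 <- lapply(eps, function(ep)
  merge(ep, win[, c("subject_id", "sd1")], by = "subject_id"))
h_raw <- pool5("sd1", eps_w1, covs)
cat(sprintf("dilution slope %.3f (lambda %.2f); corrected per-5 HR %.3f\n",
            ros$slope, ros$lambda, exp(ros$lambda * log(h_raw[1]))))

# grouped analysis with floating absolute risks (first imputation shown)
ep1 <- eps[[1]]
ep1$var_group <- droplevels(assign_variability_group(ep1$usual_sd))
lev <- levels(ep1$var_group)
fg <- fit_cox(ep1, c("var_group", covs))
fl <- floated_absolute_risks(fg, paste0("var_group", lev[-1]),
                             ref_label = lev[1])
print(fl, digits = 3)
cat(sprintf("pairwise-variance reproduction residual: %.1f%%\n",
            100 * attr(fl, "max_rel_residual")))

# restricted cubic spline: evidence against log-linearity?
kn <- unname(quantile(ep1$usual_sd, c(0.1, 0.5, 0.9)))
B <- rcs_basis(ep1$usual_sd, knots = kn)
ep1$sd_lin <- B[, "lin"]; ep1$sd_nl1 <- B[, "nl1"]
fs <- fit_cox(ep1, c("sd_lin", "sd_nl1", covs))
zs <- fs$coefficients[["sd_nl1"]] / sqrt(fs$vcov["sd_nl1", "sd_nl1"])
cat(sprintf("spline nonlinearity z = %.2f (log-linear if |z| < 2)\n", zs))

sub <- run_subgroup_analyses(ep1, subgroup_vars = "male",
                             covariates = c("usual_sd", covs))
write.csv(sub, "results/forest.csv", row.names = FALSE)

hr_tab <- rbind(
  data.frame(analysis = "per5_usual", group = "per 5 mm Hg",
             hr = h_usual[1], lo = h_usual[2], hi = h_usual[3]),
  data.frame(analysis = "per5_naive", group = "per 5 mm Hg",
             hr = h_naive[1], lo = h_naive[2], hi = h_naive[3]),
  data.frame(analysis = "grouped_floated", group = fl$group,
             hr = fl$hr, lo = fl$lo, hi = fl$hi))
write.csv(hr_tab, "results/hr_table.csv", row.names = FALSE)
cat("wrote results/hr_table.csv + results/forest.csv\n")
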
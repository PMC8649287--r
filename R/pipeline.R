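default_adjustment <- function() {
  c("usual_sbp", "age", "male", "smoking", "bmi", "hba1c", "ldl_c", "dbp",
    "egfr", "charlson", "oad", "insulin", "acei_arb", "beta_blocker", "ccb",
    "diuretic", "other_antihtn", "lipid_lowering", "age_band")
}

#' Run the full variability-outcome analysis pipeline
#'
#' Simulates (or accepts) a cohort, excludes subjects with too few readings,
#' estimates usual SBP and usual SBP variability by the hierarchical model,
#' multiply-imputes missing baseline covariates, Lexis-splits follow-up on
#' attained age, fits the requested Cox models on every completed data set
#' and pools them by Rubin's rules, and tabulates incidence with exact
#' Poisson intervals.
#'
#' @param config a [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort optionally, a pre-built [simulate_cohort()]-shaped list.
#' @param mcmc an [mcmc_control()] for the variability model.
#' @param min_readings minimum SBP readings per subject (default 4).
#' @param m_imputations number of imputations (default 5).
#' @param n_cycles chained-equation cycles (default 5).
#' @param analyses subset of `c("per5", "grouped", "naive", "rosner",
#'   "incidence", "age_specific", "spline", "subgroups")`.
#' @param covariates adjustment terms for the Cox models (the exposure is
#'   added automatically).
#' @param subgroup_vars stratifiers for `"subgroups"`.
#' @param out_dir when non-`NULL`, delimited outputs and a JSON manifest are
#'   written there.
#' @return list of class `bpv_pipeline` with elements `cohort`, `records`,
#'   `fit`, `naive`, `usual` (merged analysis table), `results` (one entry
#'   per requested analysis), and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         mcmc = mcmc_control(seed = config$seed),
                         min_readings = 4, m_imputations = 5, n_cycles = 5,
                         analyses = c("per5", "grouped", "naive", "rosner",
                                      "incidence"),
                         covariates = default_adjustment(),
                         subgroup_vars = c("male", "smoking"),
                         out_dir = NULL) {
  t0 <- Sys.time()
  stage <- "simulate"
  res <- list()
  tryCatch({
    if (is.null(cohort)) cohort <- simulate_cohort(config)

    stage <- "filter"
    records <- filter_min_records(cohort$longitudinal, min_readings)

    stage <- "variability_fit"
    fit <- fit_usual_bp(records, mcmc = mcmc)
    naive <- naive_subject_stats(records)

    stage <- "merge"
    truth <- cohort$truth
    usual <- merge(fit$subjects[, c("subject_id", "usual_sbp", "usual_sd",
                                    "sd_usual_sbp", "sd_usual_sd")],
                   naive[, c("subject_id", "naive_sd", "mean_sbp")],
                   by = "subject_id")
    usual$subject_id <- as.integer(usual$subject_id)
    base <- merge(cohort$baseline, usual, by = "subject_id")
    base <- merge(base,
                  truth[, c("subject_id", "time_years", "event", "sigma_i")],
                  by = "subject_id")
    if (any(base$time_years <= 0)) base <- base[base$time_years > 0, ]

    stage <- "imputation"
    imp_cols <- intersect(names(cohort$config$covariate_missing_rates),
                          names(base))
    imp_frame <- base[, c(imp_cols,
                          setdiff(c("age", "male", "usual_sbp", "usual_sd",
                                    "event"), imp_cols))]
    imp_frame$log_time <- log(base$time_years)
    imps <- impute_chained(imp_frame, m = m_imputations, n_cycles = n_cycles,
                           imputable = imp_cols, exclude = character(),
                           seed = cohort$config$seed + 7L)
    completed <- lapply(imps, function(d) {
      out <- base
      out[imp_cols] <- d[imp_cols]
      out
    })

    stage <- "lexis"
    episodes <- lapply(completed, lexis_split)
    res$n_episodes <- nrow(episodes[[1]])

    stage <- "cox"
    pool_per5 <- function(term, eps_list, covs) {
      per <- lapply(eps_list, function(ep) {
        f <- fit_cox(ep, c(term, covs))
        per5_continuous_hr(f, term = term)
      })
      p <- rubin_pool(vapply(per, `[[`, 0, "log_hr"),
                      vapply(per, `[[`, 0, "se")^2)
      list(hr = exp(p$qbar), lo = exp(p$lo), hi = exp(p$hi),
           log_hr = p$qbar, se = p$se, pooled = p)
    }

    if ("per5" %in% analyses)
      res$per5 <- pool_per5("usual_sd", episodes, covariates)

    if ("naive" %in% analyses) {
      covs_naive <- c(setdiff(covariates, "usual_sbp"), "mean_sbp")
      res$naive_per5 <- pool_per5("naive_sd", episodes, covs_naive)
    }

    if ("rosner" %in% analyses) {
      stage <- "rosner"
      win <- window_variability(records)
      res$rosner <- rosner_dilution_ratio(win$sd1, win$sd2)
      eps_w1 <- lapply(episodes, function(ep) {
        m <- merge(ep, win[, c("subject_id", "sd1")], by = "subject_id")
        m[!is.na(m$sd1), ]
      })
      raw <- pool_per5("sd1", eps_w1, covariates)
      res$rosner_per5 <- list(
        raw_log_hr = raw$log_hr,
        log_hr = rosner_correct(raw$log_hr, res$rosner),
        hr = exp(rosner_correct(raw$log_hr, res$rosner)),
        lambda = res$rosner$lambda)
    }

    if ("grouped" %in% analyses) {
      stage <- "grouped"
      grp_eps <- lapply(episodes, function(ep) {
        g <- assign_variability_group(ep$usual_sd)
        # a group needs events in every imputation to be estimable; empty
        # or event-free groups are dropped with a warning
        ev <- tapply(ep$event, g, sum, default = 0)
        keep <- names(ev)[ev > 0]
        if (length(keep) < length(levels(g)))
          warning("dropping variability groups without events: ",
                  paste(setdiff(levels(g), keep), collapse = ", "))
        ep <- ep[as.character(g) %in% keep, ]
        ep$var_group <- factor(as.character(g[as.character(g) %in% keep]),
                               levels = keep)
        ep
      })
      lev <- levels(grp_eps[[1]]$var_group)
      terms <- paste0("var_group", lev[-1])
      per_imp <- lapply(grp_eps, function(ep) {
        f <- fit_cox(ep, c("var_group", setdiff(covariates, "usual_sd")))
        floated_absolute_risks(f, terms, ref_label = lev[1])
      })
      pooled <- lapply(seq_along(lev), function(g) {
        rubin_pool(vapply(per_imp, function(fl) fl$log_hr[g], 0),
                   vapply(per_imp, function(fl) fl$floated_var[g], 0))
      })
      res$grouped <- data.frame(
        group = lev,
        log_hr = vapply(pooled, `[[`, 0, "qbar"),
        hr = exp(vapply(pooled, `[[`, 0, "qbar")),
        lo = exp(vapply(pooled, `[[`, 0, "lo")),
        hi = exp(vapply(pooled, `[[`, 0, "hi")))
      res$grouped_residual <-
        max(vapply(per_imp, function(fl) attr(fl, "max_rel_residual"), 0))
    }

    if ("incidence" %in% analyses) {
      stage <- "incidence"
      grp <- assign_variability_group(usual$usual_sd)
      names(grp) <- as.character(usual$subject_id)
      outc <- cohort$outcomes
      outc <- outc[as.character(outc$subject_id) %in% names(grp) &
                     outc$time_years > 0, ]
      res$incidence <- incidence_table(outc, grp)
    }

    if ("age_specific" %in% analyses) {
      stage <- "age_specific"
      hd_terms <- "usual_sd:half_decade_band"
      per_dec <- lapply(episodes, function(ep) {
        ep$half_decade_band <- droplevels(ep$half_decade_band)
        f <- fit_cox(ep, c("half_decade_band", hd_terms,
                           setdiff(covariates, "age_band")))
        lv <- levels(ep$half_decade_band)
        cn <- paste0("usual_sd:half_decade_band", lv)
        decades <- split(seq_along(lv), (seq_along(lv) - 1) %/% 2)
        lapply(decades, function(ix) {
          if (length(ix) == 2 && all(cn[ix] %in% names(f$coefficients))) {
            d <- decade_hr_geometric(f, cn[ix[1]], cn[ix[2]])
            c(log_hr = 5 * d$log_hr, var = 25 * d$var)
          } else c(log_hr = NA_real_, var = NA_real_)
        })
      })
      n_dec <- length(per_dec[[1]])
      res$age_specific <- do.call(rbind, lapply(seq_len(n_dec), function(d) {
        lh <- vapply(per_dec, function(x) x[[d]][["log_hr"]], 0)
        vv <- vapply(per_dec, function(x) x[[d]][["var"]], 0)
        if (any(!is.finite(lh))) return(NULL)
        p <- rubin_pool(lh, vv)
        data.frame(decade = sprintf("%d-%d", 45 + 10 * (d - 1),
                                    54 + 10 * (d - 1)),
                   hr_per5 = exp(p$qbar), lo = exp(p$lo), hi = exp(p$hi))
      }))
    }

    if ("spline" %in% analyses) {
      stage <- "spline"
      kn <- unname(stats::quantile(usual$usual_sd, c(0.1, 0.5, 0.9)))
      sp_eps <- lapply(episodes, function(ep) {
        bb <- rcs_basis(ep$usual_sd, knots = kn)
        ep$sd_lin <- bb[, "lin"]; ep$sd_nl1 <- bb[, "nl1"]
        ep
      })
      per <- lapply(sp_eps, function(ep) {
        f <- fit_cox(ep, c("sd_lin", "sd_nl1",
                           setdiff(covariates, "usual_sd")))
        c(b = f$coefficients[["sd_nl1"]], v = f$vcov["sd_nl1", "sd_nl1"])
      })
      p <- rubin_pool(vapply(per, `[`, 0, 1), vapply(per, `[`, 0, 2))
      res$spline <- list(knots = kn, nl_coef = p$qbar, nl_se = p$se,
                         nl_p = 2 * stats::pt(-abs(p$qbar / p$se),
                                              df = max(p$df, 1)))
    }

    if ("subgroups" %in% analyses) {
      stage <- "subgroups"
      res$subgroups <- run_subgroup_analyses(
        episodes[[1]], term = "usual_sd", subgroup_vars = subgroup_vars,
        covariates = c("usual_sd", covariates))
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("bpvar")),
      seed = cohort$config$seed,
      n_subjects = cohort$config$n_subjects,
      n_analysed = nrow(base),
      min_readings = min_readings,
      m_imputations = m_imputations,
      mcmc = unclass(mcmc),
      max_rhat = max(fit$diagnostics$rhat),
      min_ess = min(fit$diagnostics$ess),
      analyses = analyses,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )

    out <- structure(list(cohort = cohort, records = records, fit = fit,
                          naive = naive, usual = usual, base = base,
                          episodes_first = episodes[[1]],
                          results = res, manifest = manifest),
                     class = "bpv_pipeline")
    if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

write_pipeline_outputs <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(x$usual, file.path(dir, "usual.csv"), row.names = FALSE)
  utils::write.csv(x$episodes_first, file.path(dir, "episodes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(diagnostics = x$fit$diagnostics, mcmc = unclass(x$fit$mcmc)),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  hr <- list()
  if (!is.null(x$results$per5))
    hr$per5 <- data.frame(analysis = "per5", group = "per 5 mm Hg",
                          hr = x$results$per5$hr, lo = x$results$per5$lo,
                          hi = x$results$per5$hi)
  if (!is.null(x$results$grouped))
    hr$grouped <- data.frame(analysis = "grouped",
                             group = x$results$grouped$group,
                             hr = x$results$grouped$hr,
                             lo = x$results$grouped$lo,
                             hi = x$results$grouped$hi)
  if (length(hr) > 0)
    utils::write.csv(do.call(rbind, hr), file.path(dir, "hr_table.csv"),
                     row.names = FALSE)
  if (!is.null(x$results$incidence))
    utils::write.csv(x$results$incidence,
                     file.path(dir, "incidence_table.csv"), row.names = FALSE)
  if (!is.null(x$results$subgroups))
    utils::write.csv(x$results$subgroups, file.path(dir, "forest.csv"),
                     row.names = FALSE)
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.bpv_pipeline <- function(x, ...) {
  cat("Usual SBP variability pipeline\n")
  cat(sprintf("  %d subjects analysed, %d episodes, max R-hat %.3f\n",
              nrow(x$base), nrow(x$episodes_first), x$manifest$max_rhat))
  if (!is.null(x$results$per5))
    cat(sprintf("  per-5 mm Hg HR (usual SD): %.3f (%.3f-%.3f)\n",
                x$results$per5$hr, x$results$per5$lo, x$results$per5$hi))
  if (!is.null(x$results$naive_per5))
    cat(sprintf("  per-5 mm Hg HR (naive SD): %.3f (%.3f-%.3f)\n",
                x$results$naive_per5$hr, x$results$naive_per5$lo,
                x$results$naive_per5$hi))
  if (!is.null(x$results$rosner_per5))
    cat(sprintf("  per-5 mm Hg HR (Rosner-corrected): %.3f (lambda %.2f)\n",
                x$results$rosner_per5$hr, x$results$rosner_per5$lambda))
  invisible(x)
}
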
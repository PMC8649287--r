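#' Restrict a longitudinal table to subjects with enough readings
#'
#' @param records data.frame with columns `subject_id`, `t_years`, `sbp`.
#' @param k minimum number of readings (default 4).
#' @return the filtered records, with attributes `n_excluded` (subjects
#'   dropped) and `excluded_ids`.
#' @export
filter_min_records <- function(records, k = 4) {
  if (k < 2) stop("k must be >= 2")
  cnt <- table(records$subject_id)
  keep_ids <- names(cnt)[cnt >= k]
  out <- records[as.character(records$subject_id) %in% keep_ids, ]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(cnt < k)
  attr(out, "excluded_ids") <- names(cnt)[cnt < k]
  out
}

#' Per-subject naive summary statistics
#'
#' Ordinary least-squares line per subject; the naive variability estimate is
#' the residual SD about that line (denominator n-2), or about the mean when
#' `detrend = FALSE` (denominator n-1). These are the person-by-person
#' statistics that suffer regression dilution when used as exposures.
#'
#' @param records data.frame with `subject_id`, `t_years`, `sbp`.
#' @param detrend remove each subject's OLS slope before computing the SD.
#' @param denominator `"df"` (default: n-2 detrended, n-1 otherwise) or
#'   `"n-1"` / `"n"` to force a denominator.
#' @return data.frame `subject_id`, `n`, `mean_sbp`, `slope`, `naive_sd`.
#'   `naive_sd` is `NA` where the denominator is not positive.
#' @export
naive_subject_stats <- function(records, detrend = TRUE,
                                denominator = c("df", "n-1", "n")) {
  denominator <- match.arg(denominator)
  if (any(table(records$subject_id) < 2)) stop("subjects with <2 readings")
  sid <- factor(records$subject_id, levels = unique(records$subject_id))
  n <- as.numeric(tapply(records$sbp, sid, length))
  sy <- as.numeric(tapply(records$sbp, sid, sum))
  st <- as.numeric(tapply(records$t_years, sid, sum))
  stt <- as.numeric(tapply(records$t_years^2, sid, sum))
  sty <- as.numeric(tapply(records$t_years * records$sbp, sid, sum))
  syy <- as.numeric(tapply(records$sbp^2, sid, sum))

  mean_sbp <- sy / n
  vt <- stt - st^2 / n
  slope <- ifelse(vt > 1e-12, (sty - st * sy / n) / vt, 0)
  ss_tot <- syy - sy^2 / n
  ss_res <- if (detrend) pmax(ss_tot - slope^2 * vt, 0) else ss_tot
  dff <- switch(denominator,
                "df" = if (detrend) n - 2 else n - 1,
                "n-1" = n - 1,
                "n" = n)
  sd_out <- ifelse(dff > 0, sqrt(ss_res / pmax(dff, 1)), NA_real_)
  sd_out[dff == 0 & ss_res < 1e-10] <- 0  # e.g. 2 points, detrended: exact fit
  data.frame(subject_id = levels(sid), n = n, mean_sbp = mean_sbp,
             slope = if (detrend) slope else NA_real_, naive_sd = sd_out,
             stringsAsFactors = FALSE)
}

#' Priors for the heteroscedastic hierarchical SBP model
#'
#' The model is `y_ij = alpha_i + beta_i t_ij + e_ij`,
#' `e_ij ~ N(0, sigma_i^2)`, `(alpha_i, beta_i) ~ BVN(mu, Sigma)`,
#' `log sigma_i ~ N(theta, omega^2)`. Priors: `mu` componentwise normal,
#' `Sigma` inverse-Wishart (weakly informative, conjugate), `theta` normal,
#' `omega` half-normal.
#'
#' @param mu_mean,mu_sd prior mean/SD for the two components of `mu`.
#' @param Sigma_df,Sigma_scale inverse-Wishart degrees of freedom and scale.
#' @param theta_mean,theta_sd normal prior for `theta` (log mm Hg scale).
#' @param omega_scale half-normal scale for `omega`.
#' @return list of class `bpv_prior`.
#' @export
mixed_model_prior <- function(mu_mean = c(0, 0), mu_sd = c(1000, 1000),
                              Sigma_df = 3, Sigma_scale = diag(c(100, 4)),
                              theta_mean = log(12), theta_sd = 1,
                              omega_scale = 1) {
  stopifnot(all(mu_sd > 0), theta_sd > 0, omega_scale > 0, Sigma_df > 1)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd, Sigma_df = Sigma_df,
                 Sigma_scale = Sigma_scale, theta_mean = theta_mean,
                 theta_sd = theta_sd, omega_scale = omega_scale),
            class = "bpv_prior")
}

#' MCMC settings for [fit_usual_bp()]
#'
#' @param chains number of chains (>= 2 for split-R-hat).
#' @param iterations post-adaptation iterations per chain (including burn-in).
#' @param burn_in iterations discarded per chain.
#' @param thin keep every `thin`-th draw.
#' @param seed integer seed; chains use derived sub-seeds.
#' @param rhat_threshold largest acceptable hyperparameter split-R-hat.
#' @param sigma_step,omega_step random-walk SDs for the log-scale Metropolis
#'   updates of `sigma_i` and `omega`.
#' @param sigma_sweeps Metropolis sweeps of the latent log-SD field (with
#'   interleaved `theta`/`omega` updates) per Gibbs scan; extra sweeps are
#'   cheap and improve hyperparameter mixing.
#' @param cov_steps,cov_step number and size of collapsed Metropolis steps
#'   for the random-effect covariance per scan (subject effects integrated
#'   out); these cross the funnel created by weakly identified slopes.
#' @param on_nonconvergence `"error"` (default) or `"warn"` when any
#'   hyperparameter split-R-hat exceeds the threshold.
#' @return list of class `bpv_mcmc`.
#' @export
mcmc_control <- function(chains = 2, iterations = 1500, burn_in = 500,
                         thin = 1, seed = 1L, rhat_threshold = 1.05,
                         sigma_step = 0.25, omega_step = 0.12,
                         sigma_sweeps = 5, cov_steps = 5, cov_step = 0.35,
                         on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(chains >= 2, iterations > burn_in, burn_in >= 0, thin >= 1,
            sigma_sweeps >= 1, cov_steps >= 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold,
                 sigma_step = sigma_step, omega_step = omega_step,
                 sigma_sweeps = as.integer(sigma_sweeps),
                 cov_steps = as.integer(cov_steps), cov_step = cov_step,
                 on_nonconvergence = on_nonconvergence),
            class = "bpv_mcmc")
}

# 2x2 symmetric inverse
inv2 <- function(m) {
  d <- m[1, 1] * m[2, 2] - m[1, 2]^2
  matrix(c(m[2, 2], -m[1, 2], -m[1, 2], m[1, 1]), 2, 2) / d
}

#' Fit the heteroscedastic hierarchical model by MCMC
#'
#' Gibbs sampling with conjugate updates for the subject effects
#' `(alpha_i, beta_i)`, the population mean `mu`, the random-effect
#' covariance `Sigma` (inverse-Wishart) and `theta`, and log-scale
#' random-walk Metropolis updates for each `sigma_i` and for `omega`.
#' "Usual SBP" and "usual SBP variability" are the posterior means of
#' `alpha_i` and `sigma_i`. Split-R-hat and effective sample size are
#' computed for every hyperparameter; the fit fails loudly (or warns, per
#' `mcmc$on_nonconvergence`) when any R-hat exceeds the threshold.
#'
#' @param records longitudinal table (`subject_id`, `t_years`, `sbp`); every
#'   subject must have at least 2 readings, not all at the same time.
#' @param prior a [mixed_model_prior()].
#' @param mcmc an [mcmc_control()].
#' @return object of class `bpv_fit`: list with `subjects` (data.frame of
#'   posterior means/SDs per subject), `hyper` (posterior means of `mu`,
#'   `Sigma`, `theta`, `omega`), `diagnostics` (data.frame of R-hat and ESS),
#'   `draws` (hyperparameter draws, chains stacked), `mcmc`, `prior`.
#' @export
fit_usual_bp <- function(records, prior = mixed_model_prior(),
                         mcmc = mcmc_control()) {
  sid <- factor(records$subject_id, levels = unique(records$subject_id))
  n_i <- as.numeric(tapply(records$sbp, sid, length))
  if (any(n_i < 2)) stop("every subject needs >= 2 readings")
  st <- as.numeric(tapply(records$t_years, sid, sum))
  stt <- as.numeric(tapply(records$t_years^2, sid, sum))
  if (any(stt - st^2 / n_i < 1e-12 & n_i >= 2))
    stop("degenerate design: a subject has all readings at the same time")
  sy <- as.numeric(tapply(records$sbp, sid, sum))
  sty <- as.numeric(tapply(records$t_years * records$sbp, sid, sum))
  syy <- as.numeric(tapply(records$sbp^2, sid, sum))
  n <- length(n_i)

  ns <- naive_subject_stats(records)
  hyper_names <- c("mu1", "mu2", "Sigma11", "Sigma12", "Sigma22",
                   "theta", "omega")
  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  draws <- array(NA_real_, c(n_keep, mcmc$chains, length(hyper_names)),
                 dimnames = list(NULL, NULL, hyper_names))
  sum_a <- sum_a2 <- sum_b <- sum_b2 <- sum_s <- sum_s2 <- numeric(n)
  total_kept <- 0L

  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 1000L * ch)
    # initial values from per-subject OLS, jittered per chain
    a <- ns$mean_sbp + stats::rnorm(n, 0, 2)
    b <- ifelse(is.na(ns$slope), 0, ns$slope) + stats::rnorm(n, 0, 0.5)
    ls <- log(pmax(ifelse(is.na(ns$naive_sd), 10, ns$naive_sd), 2)) +
      stats::rnorm(n, 0, 0.2)
    mu <- c(mean(a), mean(b))
    Sigma <- diag(c(max(stats::var(a), 1), max(stats::var(b), 0.25)))
    theta <- mean(ls)
    omega <- max(stats::sd(ls), 0.05)

    prior_prec_mu <- diag(1 / prior$mu_sd^2)
    prior_b_mu <- prior_prec_mu %*% prior$mu_mean
    kept <- 0L
    for (it in seq_len(mcmc$iterations)) {
      s2 <- exp(2 * ls)
      # --- Sigma | y, mu, sigma (subject effects integrated out):
      # random-walk Metropolis on (log S11, log S22, atanh rho). The
      # collapsed update crosses the funnel between Sigma and the weakly
      # identified slopes; the effects are re-imputed immediately after.
      rr <- syy - 2 * mu[1] * sy - 2 * mu[2] * sty + mu[1]^2 * n_i +
        2 * mu[1] * mu[2] * st + mu[2]^2 * stt
      u1 <- sy - mu[1] * n_i - mu[2] * st
      u2 <- sty - mu[1] * st - mu[2] * stt
      log_marg_post <- function(Sig) {
        Si <- inv2(Sig)
        ld <- log(Sig[1, 1] * Sig[2, 2] - Sig[1, 2]^2)
        p11 <- Si[1, 1] + n_i / s2
        p12 <- Si[1, 2] + st / s2
        p22 <- Si[2, 2] + stt / s2
        dt <- p11 * p22 - p12^2
        quad <- rr / s2 -
          (p22 * u1^2 - 2 * p12 * u1 * u2 + p11 * u2^2) / (dt * s2^2)
        marg <- -0.5 * (n * ld + sum(log(dt)) + sum(quad))
        pri <- -0.5 * (prior$Sigma_df + 3) * ld -
          0.5 * (prior$Sigma_scale[1, 1] * Si[1, 1] +
                   2 * prior$Sigma_scale[1, 2] * Si[1, 2] +
                   prior$Sigma_scale[2, 2] * Si[2, 2])
        rho <- Sig[1, 2] / sqrt(Sig[1, 1] * Sig[2, 2])
        jac <- 1.5 * (log(Sig[1, 1]) + log(Sig[2, 2])) + log(1 - rho^2)
        marg + pri + jac
      }
      par0 <- c(log(Sigma[1, 1]), log(Sigma[2, 2]),
                atanh(Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2])))
      lp0 <- log_marg_post(Sigma)
      for (k in seq_len(mcmc$cov_steps)) {
        par1 <- par0 + stats::rnorm(3, 0, mcmc$cov_step)
        r1 <- tanh(par1[3])
        S1 <- exp(par1[1]); S2 <- exp(par1[2])
        Sig1 <- matrix(c(S1, r1 * sqrt(S1 * S2), r1 * sqrt(S1 * S2), S2), 2, 2)
        lp1 <- log_marg_post(Sig1)
        if (log(stats::runif(1)) < lp1 - lp0) {
          Sigma <- Sig1; par0 <- par1; lp0 <- lp1
        }
      }
      Si <- inv2(Sigma)
      p11 <- Si[1, 1] + n_i / s2
      p12 <- Si[1, 2] + st / s2
      p22 <- Si[2, 2] + stt / s2
      dt <- p11 * p22 - p12^2
      # --- mu | y, Sigma, sigma (subject effects integrated out):
      # exact Gaussian draw via Woodbury; removes the mu <-> effects coupling
      pi11 <- p22 / dt; pi12 <- -p12 / dt; pi22 <- p11 / dt
      mp11 <- n_i * pi11 + st * pi12
      mp12 <- n_i * pi12 + st * pi22
      mp21 <- st * pi11 + stt * pi12
      mp22 <- st * pi12 + stt * pi22
      s4 <- s2^2
      A11 <- sum(n_i / s2 - (mp11 * n_i + mp12 * st) / s4)
      A12 <- sum(st / s2 - (mp11 * st + mp12 * stt) / s4)
      A22 <- sum(stt / s2 - (mp21 * st + mp22 * stt) / s4)
      q1 <- pi11 * sy + pi12 * sty
      q2 <- pi12 * sy + pi22 * sty
      rhs <- c(sum(sy / s2 - (n_i * q1 + st * q2) / s4),
               sum(sty / s2 - (st * q1 + stt * q2) / s4)) + prior_b_mu
      Amat <- matrix(c(A11, A12, A12, A22), 2, 2) + prior_prec_mu
      V <- inv2(Amat)
      mu <- as.numeric(V %*% rhs) + as.numeric(t(chol(V)) %*% stats::rnorm(2))
      # --- (alpha_i, beta_i) | rest : conjugate bivariate normal
      r1 <- Si[1, 1] * mu[1] + Si[1, 2] * mu[2] + sy / s2
      r2 <- Si[1, 2] * mu[1] + Si[2, 2] * mu[2] + sty / s2
      m1 <- (p22 * r1 - p12 * r2) / dt
      m2 <- (p11 * r2 - p12 * r1) / dt
      l11 <- sqrt(p11)
      l21 <- p12 / l11
      l22 <- sqrt(pmax(p22 - l21^2, 1e-12))
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      u2 <- z2 / l22
      u1 <- (z1 - l21 * u2) / l11
      a <- m1 + u1
      b <- m2 + u2
      # --- Sigma | rest : inverse-Wishart
      da <- a - mu[1]; db <- b - mu[2]
      S <- prior$Sigma_scale +
        matrix(c(sum(da^2), sum(da * db), sum(da * db), sum(db^2)), 2, 2)
      W <- stats::rWishart(1, prior$Sigma_df + n, inv2(S))[, , 1]
      Sigma <- inv2(W)
      # --- sigma_i, theta, omega: several interleaved sweeps per scan.
      # The latent log-SD field and its hyperparameters are strongly
      # coupled; extra cheap sweeps restore mixing of theta and omega.
      ss <- pmax(syy - 2 * a * sy - 2 * b * sty + a^2 * n_i +
                   2 * a * b * st + b^2 * stt, 1e-12)
      lp <- function(l) -n_i * l - ss / 2 * exp(-2 * l) -
        (l - theta)^2 / (2 * omega^2)
      for (sw in seq_len(mcmc$sigma_sweeps)) {
        # sigma_i | rest : log-scale random-walk Metropolis (vectorised)
        ls_new <- ls + stats::rnorm(n, 0, mcmc$sigma_step)
        acc <- log(stats::runif(n)) < lp(ls_new) - lp(ls)
        ls[acc] <- ls_new[acc]
        # theta | rest : conjugate normal
        prc <- n / omega^2 + 1 / prior$theta_sd^2
        mn <- (sum(ls) / omega^2 + prior$theta_mean / prior$theta_sd^2) / prc
        theta <- stats::rnorm(1, mn, sqrt(1 / prc))
        # omega | rest : log-scale Metropolis, half-normal prior
        ssl <- sum((ls - theta)^2)
        lpo <- function(v) -n * v - ssl / 2 * exp(-2 * v) -
          exp(2 * v) / (2 * prior$omega_scale^2) + v
        v0 <- log(omega)
        v1 <- v0 + stats::rnorm(1, 0, mcmc$omega_step)
        if (log(stats::runif(1)) < lpo(v1) - lpo(v0)) omega <- exp(v1)
        # joint scale move: rescale (omega, latent field) about theta.
        # Prior and Jacobian terms cancel; only the likelihood decides.
        cc <- exp(stats::rnorm(1, 0, mcmc$omega_step))
        ls_sc <- theta + cc * (ls - theta)
        llr <- sum(-n_i * (ls_sc - ls) -
                     ss / 2 * (exp(-2 * ls_sc) - exp(-2 * ls)))
        om1 <- cc * omega
        lpr <- (-om1^2 + omega^2) / (2 * prior$omega_scale^2) + log(cc)
        if (log(stats::runif(1)) < llr + lpr) {
          ls <- ls_sc
          omega <- om1
        }
      }

      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0) {
        kept <- kept + 1L
        draws[kept, ch, ] <- c(mu, Sigma[1, 1], Sigma[1, 2], Sigma[2, 2],
                               theta, omega)
        sig <- exp(ls)
        sum_a <- sum_a + a; sum_a2 <- sum_a2 + a^2
        sum_b <- sum_b + b; sum_b2 <- sum_b2 + b^2
        sum_s <- sum_s + sig; sum_s2 <- sum_s2 + sig^2
        total_kept <- total_kept + 1L
      }
    }
  }

  pm <- function(s) s / total_kept
  psd <- function(s, s2) sqrt(pmax(s2 / total_kept - (s / total_kept)^2, 0))
  subjects <- data.frame(
    subject_id = levels(sid), n = n_i,
    usual_sbp = pm(sum_a), usual_slope = pm(sum_b), usual_sd = pm(sum_s),
    sd_usual_sbp = psd(sum_a, sum_a2), sd_usual_slope = psd(sum_b, sum_b2),
    sd_usual_sd = psd(sum_s, sum_s2), stringsAsFactors = FALSE)

  diag_df <- data.frame(
    parameter = hyper_names,
    mean = apply(draws, 3, mean),
    rhat = apply(draws, 3, function(m) split_rhat(m)),
    ess = apply(draws, 3, function(m) ess_mean(m)))
  hy <- diag_df$mean
  names(hy) <- hyper_names
  hyper <- list(mu = c(hy[["mu1"]], hy[["mu2"]]),
                Sigma = matrix(c(hy[["Sigma11"]], hy[["Sigma12"]],
                                 hy[["Sigma12"]], hy[["Sigma22"]]), 2, 2),
                theta = hy[["theta"]], omega = hy[["omega"]])

  bad <- diag_df$parameter[diag_df$rhat > mcmc$rhat_threshold]
  if (length(bad) > 0) {
    msg <- sprintf("MCMC did not converge: split-R-hat > %.3f for %s",
                   mcmc$rhat_threshold, paste(bad, collapse = ", "))
    if (mcmc$on_nonconvergence == "error") stop(msg) else warning(msg)
  }

  structure(list(subjects = subjects, hyper = hyper, diagnostics = diag_df,
                 draws = draws, mcmc = mcmc, prior = prior),
            class = "bpv_fit")
}

#' @export
print.bpv_fit <- function(x, ...) {
  cat("Heteroscedastic hierarchical SBP model fit\n")
  cat(sprintf("  subjects: %d   chains: %d   kept draws/chain: %d\n",
              nrow(x$subjects), x$mcmc$chains, dim(x$draws)[1]))
  cat(sprintf("  theta = %.3f  omega = %.3f  (pop. median sigma %.2f mm Hg)\n",
              x$hyper$theta, x$hyper$omega, exp(x$hyper$theta)))
  cat(sprintf("  max split-R-hat = %.3f  min ESS = %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

# split-R-hat (Gelman-Rubin on half-chains); m = draws x chains matrix
split_rhat <- function(m) {
  n <- nrow(m)
  half <- n %/% 2
  seqs <- do.call(cbind, lapply(seq_len(ncol(m)), function(j)
    cbind(m[seq_len(half), j], m[(n - half + 1):n, j])))
  nn <- nrow(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size for the mean (Geyer initial-positive-pair truncation)
ess_mean <- function(m) {
  n <- nrow(m)
  nch <- ncol(m)
  acov <- sapply(seq_len(nch), function(j) {
    x <- m[, j] - mean(m[, j])
    stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE,
               type = "covariance", demean = FALSE)$acf[, 1, 1]
  })
  mean_var <- mean(apply(m, 2, stats::var))
  if (mean_var <= 0) return(n * nch)
  rho <- rowMeans(acov) / mean_var
  tau <- 1
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(n * nch / tau, 1)
}

#' Per-window naive variability estimates for Rosner's method
#'
#' Splits each subject's readings at `split_years` (first vs second year by
#' default) and computes the naive SD about the window mean (denominator
#' n-1) in each window, for subjects with at least `min_per_window` readings
#' in both windows.
#'
#' @param records longitudinal table.
#' @param split_years window boundary in years; readings with
#'   `t_years <= split_years` fall in the first window.
#' @param min_per_window minimum readings per window (default 2).
#' @return data.frame `subject_id`, `sd1`, `sd2`, `n1`, `n2`.
#' @export
window_variability <- function(records, split_years = 1, min_per_window = 2) {
  w1 <- records[records$t_years <= split_years, ]
  w2 <- records[records$t_years > split_years, ]
  f <- function(w) {
    if (nrow(w) == 0) return(NULL)
    cnt <- table(w$subject_id)
    keep <- names(cnt)[cnt >= min_per_window]
    w <- w[as.character(w$subject_id) %in% keep, ]
    if (nrow(w) == 0) return(NULL)
    naive_subject_stats(w, detrend = FALSE, denominator = "n-1")
  }
  s1 <- f(w1); s2 <- f(w2)
  if (is.null(s1) || is.null(s2)) stop("a window has no eligible subjects")
  m <- merge(s1[, c("subject_id", "n", "naive_sd")],
             s2[, c("subject_id", "n", "naive_sd")],
             by = "subject_id", suffixes = c("1", "2"))
  data.frame(subject_id = m$subject_id, sd1 = m$naive_sd1, sd2 = m$naive_sd2,
             n1 = m$n1, n2 = m$n2, stringsAsFactors = FALSE)
}

#' Rosner's regression-dilution ratio
#'
#' Regresses the second-window variability estimate on the first-window
#' estimate; the attenuation slope `b` of that regression estimates the
#' reliability of a single-window measurement, and the dilution ratio
#' `lambda = 1/b` is the multiplier applied to a naive log hazard ratio to
#' correct it for regression dilution.
#'
#' @param first,second paired per-subject variability estimates from two
#'   non-overlapping reading windows.
#' @return list of class `bpv_rosner`: `slope` (b), `lambda` (1/b), `n`.
#' @export
rosner_dilution_ratio <- function(first, second) {
  ok <- is.finite(first) & is.finite(second)
  first <- first[ok]; second <- second[ok]
  if (length(first) < 3) stop("need at least 3 complete pairs")
  v <- stats::var(first)
  if (v <= 0) stop("zero variance in first-window estimates")
  b <- stats::cov(first, second) / v
  structure(list(slope = b, lambda = 1 / b, n = length(first)),
            class = "bpv_rosner")
}

#' Correct a naive log hazard ratio for regression dilution
#'
#' @param log_hr naive log hazard ratio estimated from a single-window (or
#'   otherwise error-prone) exposure.
#' @param ratio a [rosner_dilution_ratio()] result.
#' @return corrected log hazard ratio `log_hr * lambda`.
#' @export
rosner_correct <- function(log_hr, ratio) {
  stopifnot(inherits(ratio, "bpv_rosner"))
  log_hr * ratio$lambda
}
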
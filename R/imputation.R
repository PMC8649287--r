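#' Multiple imputation by chained equations
#'
#' Fills missing covariate cells with `m` independent chained-equation
#' streams. Each incomplete variable gets a Bayesian-draw conditional model
#' given all other predictors: linear regression for continuous variables,
#' logistic regression for binary ones (posterior draws of the coefficients
#' and, for linear models, of the residual variance, so imputations are
#' proper). Cells are initialised by random draws from the observed values
#' and the variable-by-variable cycle is repeated `n_cycles` times.
#'
#' @param data data.frame; missingness is only allowed in columns listed in
#'   `imputable` (default: every column with an `NA`).
#' @param m number of completed tables (default 5).
#' @param n_cycles chained-equation cycles per stream (default 10).
#' @param imputable columns eligible for imputation.
#' @param predictors columns used as predictors (default: all columns except
#'   `exclude`); include outcome indicators and follow-up time here.
#' @param exclude columns never imputed and never used as predictors
#'   (e.g. identifiers).
#' @param pmm use predictive mean matching (nearest observed value to the
#'   drawn mean) instead of regression draws for continuous variables.
#' @param seed integer seed; stream k uses `seed + k`.
#' @return list of `m` completed data.frames (class `bpv_mids`).
#' @export
impute_chained <- function(data, m = 5, n_cycles = 10,
                           imputable = NULL, predictors = NULL,
                           exclude = "subject_id", pmm = FALSE,
                           seed = 1L) {
  has_na <- names(data)[vapply(data, function(x) any(is.na(x)), logical(1))]
  if (is.null(imputable)) imputable <- setdiff(has_na, exclude)
  stray <- setdiff(has_na, imputable)
  if (length(stray) > 0)
    stop("missing values in non-imputable columns: ",
         paste(stray, collapse = ", "))
  if (is.null(predictors)) predictors <- setdiff(names(data), exclude)
  for (v in imputable)
    if (all(is.na(data[[v]]))) stop("variable missing for all rows: ", v)
  if (length(has_na) == 0) {
    out <- rep(list(data), m)
    class(out) <- "bpv_mids"
    return(out)
  }

  # order incomplete variables by increasing missingness
  miss_n <- vapply(imputable, function(v) sum(is.na(data[[v]])), numeric(1))
  todo <- imputable[miss_n > 0][order(miss_n[miss_n > 0])]
  is_bin <- vapply(todo, function(v) {
    u <- unique(data[[v]][!is.na(data[[v]])])
    is.logical(data[[v]]) || length(u) <= 2
  }, logical(1))
  names(is_bin) <- todo

  out <- vector("list", m)
  for (k in seq_len(m)) {
    set.seed(seed + k)
    comp <- data
    for (v in todo) {  # initialise from observed margins
      mis <- is.na(comp[[v]])
      comp[[v]][mis] <- sample(comp[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (cyc in seq_len(n_cycles)) {
      for (v in todo) {
        mis <- is.na(data[[v]])
        preds <- setdiff(predictors, v)
        X <- stats::model.matrix(~ ., data = comp[, preds, drop = FALSE])
        yobs <- data[[v]][!mis]
        Xobs <- X[!mis, , drop = FALSE]
        Xmis <- X[mis, , drop = FALSE]
        qr_ok <- qr(Xobs)
        use <- qr_ok$pivot[seq_len(qr_ok$rank)]
        Xobs <- Xobs[, use, drop = FALSE]
        Xmis <- Xmis[, use, drop = FALSE]
        if (is_bin[[v]]) {
          y01 <- as.numeric(yobs == max(yobs))
          fit <- suppressWarnings(
            stats::glm.fit(Xobs, y01, family = stats::binomial()))
          bhat <- fit$coefficients
          w <- fit$weights
          XtWX <- crossprod(Xobs * sqrt(w))
          Vb <- tryCatch(solve(XtWX), error = function(e)
            diag(1e-4, length(bhat)))
          bstar <- bhat + as.numeric(t(chol(Vb)) %*% stats::rnorm(length(bhat)))
          p <- stats::plogis(as.numeric(Xmis %*% bstar))
          drawn <- stats::rbinom(length(p), 1, p)
          vals <- sort(unique(yobs))
          comp[[v]][mis] <- if (length(vals) == 2)
            vals[drawn + 1] else vals[1]
        } else {
          fit <- stats::lm.fit(Xobs, yobs)
          bhat <- fit$coefficients
          df <- length(yobs) - length(bhat)
          ssr <- sum(fit$residuals^2)
          s2star <- ssr / stats::rchisq(1, max(df, 1))
          XtX_inv <- chol2inv(qr.R(fit$qr))
          bstar <- bhat + as.numeric(t(chol(s2star * XtX_inv)) %*%
                                       stats::rnorm(length(bhat)))
          mu_mis <- as.numeric(Xmis %*% bstar)
          if (pmm) {
            mu_obs <- as.numeric(Xobs %*% bstar)
            idx <- vapply(mu_mis, function(mm)
              which.min(abs(mu_obs - mm)), integer(1))
            comp[[v]][mis] <- yobs[idx]
          } else {
            comp[[v]][mis] <- mu_mis +
              stats::rnorm(length(mu_mis), 0, sqrt(s2star))
          }
        }
      }
    }
    out[[k]] <- comp
  }
  class(out) <- "bpv_mids"
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' `Qbar = mean(Q)`, `Wbar = mean(U)`, `B = var(Q)`,
#' `T = Wbar + (1 + 1/m) B`, with small-m degrees of freedom
#' `(m - 1) (1 + Wbar / ((1 + 1/m) B))^2`; with `m = 1` (or `B = 0`)
#' `T = Wbar` and the df are infinite.
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @param conf confidence level.
#' @return list of class `bpv_pooled`: `qbar`, `wbar`, `b`, `t`, `se`, `m`,
#'   `df`, `lo`, `hi`.
#' @export
rubin_pool <- function(estimates, variances, conf = 0.95) {
  m <- length(estimates)
  if (m < 1 || length(variances) != m) stop("need m >= 1 matched inputs")
  if (any(!is.finite(estimates)) || any(!is.finite(variances)))
    stop("estimates and variances must be finite")
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- if (m > 1) stats::var(estimates) else 0
  tt <- wbar + (1 + 1 / m) * b
  df <- if (m > 1 && b > 0) (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2 else Inf
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf) / 2, df)
       else stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(tt)
  structure(list(qbar = qbar, wbar = wbar, b = b, t = tt, se = se, m = m,
                 df = df, lo = qbar - q * se, hi = qbar + q * se),
            class = "bpv_pooled")
}

#' @export
print.bpv_pooled <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate (m = %d): %.4f (SE %.4f), 95%% CI %.4f to %.4f\n",
              x$m, x$qbar, x$se, x$lo, x$hi))
  cat(sprintf("  within %.5f  between %.5f  total %.5f  df %.1f\n",
              x$wbar, x$b, x$t, x$df))
  invisible(x)
}
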
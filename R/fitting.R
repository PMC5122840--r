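# Interaction model fitting: Cox proportional hazards (partial likelihood,
# Breslow ties) and ordinary least squares, each returning the interaction
# coefficient, its standard error, and a two-sided Wald p-value.

fit_summary <- function(gamma, se_gamma, p_value, converged, model) {
  structure(list(gamma = gamma, se_gamma = se_gamma, p_value = p_value,
                 converged = converged, model = model),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("%s interaction fit: gamma = %.4f (SE %.4f), p = %.3g%s\n",
              x$model, x$gamma, x$se_gamma, x$p_value,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

failed_fit <- function(model) {
  fit_summary(NA_real_, NA_real_, NA_real_, FALSE, model)
}

#' Fit the Cox interaction model to one simulated trial
#'
#' Maximizes the Cox partial likelihood with covariates
#' \{GRS, arm, GRS x arm\} using Breslow handling of tied times, and returns
#' the interaction coefficient, its model-based standard error from the
#' inverse observed information, and a two-sided Wald p-value. The analysis
#' model always uses the aggregate GRS even when the data were generated
#' per SNP; this generator/analysis mismatch mirrors how a GRS trial would
#' be analysed and is intentional.
#'
#' Fits with fewer than one event per arm, zero GRS variance in the cohort,
#' non-convergence, or a monotone partial likelihood (separation) are
#' flagged `converged = FALSE` rather than raising an error, so a
#' Monte-Carlo loop can drop them from the power tally.
#'
#' @param time follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param grs per-participant genetic risk score.
#' @param arm treatment indicator (1 = active, 0 = placebo).
#' @return A `fit_summary`.
#' @export
fit_cox_interaction <- function(time, event, grs, arm) {
  n <- length(time)
  if (length(event) != n || length(grs) != n || length(arm) != n)
    stop_invalid_input("time, event, grs and arm must have equal length")
  if (sum(event[arm == 1]) < 1 || sum(event[arm == 0]) < 1) return(failed_fit("survival"))
  if (var(grs) == 0) return(failed_fit("survival"))
  x <- cbind(grs = as.numeric(grs), arm = as.numeric(arm),
             grs_x_arm = as.numeric(grs * arm))
  y <- survival::Surv(as.numeric(time), as.numeric(event))
  ctrl <- survival::coxph.control()
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                          control = ctrl, weights = NULL,
                          method = "breslow", rownames = NULL)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || anyNA(fit$coefficients)) return(failed_fit("survival"))
  gamma <- unname(fit$coefficients[3])
  v <- fit$var[3, 3]
  if (!is.finite(gamma) || !is.finite(v) || v <= 0) return(failed_fit("survival"))
  se <- sqrt(v)
  # monotone-likelihood / separation guard: coefficient drifting to +-Inf
  if (abs(gamma) > 15 || se > 50 || fit$iter >= ctrl$iter.max)
    return(failed_fit("survival"))
  p <- 2 * pnorm(-abs(gamma) / se)
  fit_summary(gamma, se, p, TRUE, "survival")
}

#' Fit the linear interaction model to one simulated trial
#'
#' Ordinary least squares of the outcome on \{1, GRS, arm, GRS x arm\}.
#' The interaction coefficient's standard error uses the usual unbiased
#' residual-variance estimator, and the two-sided p-value uses the t
#' reference distribution on `n - 4` degrees of freedom.
#'
#' @param y outcome vector (observed, possibly error-contaminated).
#' @param grs per-participant genetic risk score.
#' @param arm treatment indicator (1 = active, 0 = placebo).
#' @return A `fit_summary`.
#' @export
fit_linear_interaction <- function(y, grs, arm) {
  n <- length(y)
  if (length(grs) != n || length(arm) != n)
    stop_invalid_input("y, grs and arm must have equal length")
  if (n <= 4) stop_infeasible_fit("need more than 4 observations")
  X <- cbind(intercept = 1, grs = as.numeric(grs), arm = as.numeric(arm),
             grs_x_arm = as.numeric(grs * arm))
  fit <- stats::lm.fit(X, as.numeric(y))
  if (fit$rank < 4L)
    stop_infeasible_fit("design matrix is rank deficient (e.g. one-arm cohort)")
  rss <- sum(fit$residuals^2)
  df <- n - 4L
  sigma2 <- rss / df
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  # undo any QR pivoting
  piv <- fit$qr$pivot
  se_all <- numeric(4)
  se_all[piv] <- sqrt(diag(xtx_inv) * sigma2)
  coefs <- fit$coefficients
  gamma <- unname(coefs["grs_x_arm"])
  se <- se_all[4]
  tstat <- gamma / se
  p <- 2 * pt(-abs(tstat), df = df)
  fit_summary(gamma, se, p, TRUE, "linear")
}
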
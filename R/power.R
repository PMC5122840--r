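# Monte-Carlo power estimation (Zero/One and Standard-Error methods) and
# minimum sample-size search.

#' Scenario configuration
#'
#' Bundles everything that defines one power scenario: the genetic
#' architecture, the sampling frame, the recruitment design, the outcome
#' model and the Monte-Carlo settings. Defaults follow the simulator's
#' reference setup: alpha 0.05, 1,000 iterations, 4-year follow-up, 37%
#' overall incidence and a 20-SNP panel.
#'
#' The panel may be given explicitly (`freqs` plus `beta_int`, optionally
#' `beta_main`) or described by ranges (`k`, `maf_range`, `effect_range`,
#' `direction`), in which case it is drawn once per scenario from the
#' scenario seed and reused across all iterations.
#'
#' @param design `"gbr"` or `"conventional"` recruitment.
#' @param outcome `"survival"` or `"quantitative"`.
#' @param frame_size genotyped sampling-frame size.
#' @param n_trial trial size (participants randomized).
#' @param k number of SNPs when the panel is drawn from ranges.
#' @param maf_range effect-allele frequency interval for a drawn panel.
#' @param effect_range absolute per-allele interaction effect interval.
#' @param direction `"protective"` or `"adverse"` interaction sign.
#' @param freqs explicit effect-allele frequencies (overrides `k`/ranges).
#' @param beta_int explicit per-allele interaction effects (with `freqs`).
#' @param beta_main per-allele marginal effects (default 0).
#' @param treatment_main treatment main effect (log-hazard or outcome units;
#'   default 0).
#' @param followup maximum follow-up, years (survival outcomes).
#' @param target_incidence overall event fraction at end of follow-up.
#' @param resid_sd residual SD of the quantitative outcome, outcome units.
#' @param r2_error squared correlation between observed and true outcome;
#'   1 means no measurement error.
#' @param alpha two-sided significance level for the interaction test.
#' @param iterations Monte-Carlo iterations.
#' @param seed master RNG seed for the scenario.
#' @param name optional scenario label.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(design = c("conventional", "gbr"),
                            outcome = c("survival", "quantitative"),
                            frame_size = 10000,
                            n_trial = 1000,
                            k = 20,
                            maf_range = c(0.2, 0.5),
                            effect_range = c(0.15, 0.30),
                            direction = "protective",
                            freqs = NULL,
                            beta_int = NULL,
                            beta_main = 0,
                            treatment_main = 0,
                            followup = 4.0,
                            target_incidence = 0.37,
                            resid_sd = 1.0,
                            r2_error = 1.0,
                            alpha = 0.05,
                            iterations = 1000,
                            seed = 1,
                            name = NULL) {
  design <- match.arg(design)
  outcome <- match.arg(outcome)
  # tolerate list-valued vectors from YAML/JSON round trips
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  maf_range <- num(maf_range); effect_range <- num(effect_range)
  freqs <- num(freqs); beta_int <- num(beta_int); beta_main <- num(beta_main)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_invalid_config("`alpha` must lie in (0, 1)")
  if (iterations < 1) stop_invalid_config("`iterations` must be at least 1")
  if (n_trial > frame_size)
    stop_invalid_config("`n_trial` cannot exceed `frame_size`")
  if (!is.null(freqs) && is.null(beta_int))
    stop_invalid_config("explicit `freqs` require explicit `beta_int`")
  cfg <- list(design = design, outcome = outcome,
              frame_size = as.integer(frame_size), n_trial = as.integer(n_trial),
              k = as.integer(k), maf_range = maf_range,
              effect_range = effect_range, direction = direction,
              freqs = freqs, beta_int = beta_int, beta_main = beta_main,
              treatment_main = treatment_main, followup = followup,
              target_incidence = target_incidence, resid_sd = resid_sd,
              r2_error = r2_error, alpha = alpha,
              iterations = as.integer(iterations), seed = as.integer(seed),
              name = name)
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario%s: %s recruitment, %s outcome\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$design, x$outcome))
  cat(sprintf("  frame %d, trial n %d, alpha %.3g, %d iterations, seed %d\n",
              x$frame_size, x$n_trial, x$alpha, x$iterations, x$seed))
  invisible(x)
}

# Materialize the scenario's panel (explicit or drawn from ranges).
resolve_panel <- function(cfg) {
  if (!is.null(cfg$freqs)) {
    snp_panel(cfg$freqs, beta_int = cfg$beta_int, beta_main = cfg$beta_main)
  } else {
    draw_panel(cfg$k, cfg$maf_range, cfg$effect_range,
               direction = cfg$direction, beta_main = cfg$beta_main)
  }
}

power_estimate <- function(power, n_used, method, mean_gamma = NA_real_,
                           mean_se_gamma = NA_real_) {
  mc_se <- if (method == "zero_one" && n_used > 0)
    sqrt(power * (1 - power) / n_used) else NA_real_
  structure(list(power = power, mc_se = mc_se, n_used = n_used,
                 method = method, mean_gamma = mean_gamma,
                 mean_se_gamma = mean_se_gamma),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Power (%s method): %.3f", x$method, x$power))
  if (is.finite(x$mc_se)) cat(sprintf(" +/- %.3f (MC SE)", x$mc_se))
  cat(sprintf(" [%d simulations]\n", x$n_used))
  invisible(x)
}

#' Zero/One power estimate from simulated p-values
#'
#' Each simulation scores 1 when its interaction p-value is strictly below
#' `alpha` and 0 otherwise; power is the mean score. The inequality is
#' strict: a p-value exactly at the threshold counts as a failure.
#'
#' @param p_values vector of interaction p-values from converged fits.
#' @param alpha significance level.
#' @return A `power_estimate` with a binomial Monte-Carlo standard error.
#' @export
power_zero_one <- function(p_values, alpha = 0.05) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0)
    stop_invalid_input("no p-values supplied")
  power_estimate(mean(p_values < alpha), length(p_values), "zero_one")
}

#' Standard-Error method power estimate
#'
#' Analytic normal-approximation power
#' `Phi(|gamma| / SE(gamma) - z_{1 - alpha/2})`, where `gamma` and
#' `SE(gamma)` are the across-iteration averages of the fitted interaction
#' effect and of its standard error (each averaged separately, then
#' ratioed).
#'
#' @param mean_gamma average fitted interaction effect.
#' @param mean_se_gamma average fitted standard error (> 0).
#' @param alpha two-sided significance level.
#' @param n_used number of simulations behind the averages (bookkeeping).
#' @return A `power_estimate`.
#' @export
power_se <- function(mean_gamma, mean_se_gamma, alpha = 0.05,
                     n_used = NA_integer_) {
  if (!is.finite(mean_se_gamma) || mean_se_gamma <= 0)
    stop_invalid_input("`mean_se_gamma` must be positive")
  pw <- pnorm(abs(mean_gamma) / mean_se_gamma - qnorm(1 - alpha / 2))
  structure(list(power = pw, mc_se = NA_real_,
                 n_used = n_used, method = "se",
                 mean_gamma = mean_gamma, mean_se_gamma = mean_se_gamma),
            class = "power_estimate")
}

#' Monte-Carlo power for one scenario
#'
#' Runs the full simulation loop: each iteration re-simulates the sampling
#' frame's genotypes, recruits the trial cohort by the configured design,
#' randomizes 1:1, simulates the outcome, fits the interaction model and
#' records the interaction coefficient, its standard error and Wald
#' p-value. Power is estimated by the Zero/One method (fraction of
#' iterations with p < alpha); for quantitative outcomes the
#' Standard-Error method is computed as a cross-check.
#'
#' The panel is drawn once from the scenario seed and held fixed; for
#' survival outcomes the baseline hazard is calibrated once against a
#' calibration frame, since incidence is a population property.
#' Iteration-level seeds are derived from the scenario seed, so results are
#' reproducible and independent of execution order. Non-converged fits are
#' dropped from both numerator and denominator; if they exceed 20% of
#' iterations the estimate is flagged unreliable.
#'
#' @param cfg a [scenario_config()].
#' @param keep_fits if `TRUE`, attach a per-iteration data frame
#'   (`iter`, `gamma`, `se`, `p`, `converged`).
#' @return An object of class `gbr_power` with elements `zero_one` (primary
#'   [power_estimate]), `se_method` (quantitative outcomes only),
#'   `mean_gamma`, `mean_se_gamma`, `n_nonconverged`, `unreliable`, `panel`,
#'   `hazard` and `cfg`.
#' @export
estimate_power <- function(cfg, keep_fits = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  seeds <- sample.int(2147483646L, cfg$iterations + 2L)

  set.seed(seeds[1])
  panel <- resolve_panel(cfg)

  hazard <- NULL
  if (cfg$outcome == "survival") {
    set.seed(seeds[2])
    calib_n <- min(cfg$frame_size, 100000L)
    calib_frame <- build_frame(panel, calib_n)
    hazard <- calibrate_baseline_hazard(calib_frame, panel, cfg$followup,
                                        cfg$target_incidence,
                                        cfg$treatment_main)
  }

  gamma <- se <- p <- rep(NA_real_, cfg$iterations)
  conv <- logical(cfg$iterations)
  for (i in seq_len(cfg$iterations)) {
    set.seed(seeds[i + 2L])
    frame <- build_frame(panel, cfg$frame_size)
    cohort <- if (cfg$design == "gbr") recruit_gbr(frame, cfg$n_trial)
              else recruit_conventional(frame, cfg$n_trial)
    cohort <- randomize_arms(cohort)
    fit <- if (cfg$outcome == "survival") {
      rec <- simulate_survival(cohort, panel, hazard, cfg$treatment_main)
      fit_cox_interaction(rec$time, rec$event, cohort$grs, cohort$arm)
    } else {
      y <- simulate_quantitative(cohort, panel, cfg$treatment_main, cfg$resid_sd)
      if (cfg$r2_error < 1) y <- add_measurement_error(y, cfg$r2_error)$y_obs
      fit_linear_interaction(y, cohort$grs, cohort$arm)
    }
    conv[i] <- fit$converged
    if (fit$converged) {
      gamma[i] <- fit$gamma; se[i] <- fit$se_gamma; p[i] <- fit$p_value
    }
  }

  n_bad <- sum(!conv)
  if (n_bad > 0)
    warning(sprintf("%d of %d fits did not converge and were dropped",
                    n_bad, cfg$iterations))
  if (all(!conv)) stop_infeasible_design("no simulated fit converged")
  mg <- mean(gamma, na.rm = TRUE)
  mse <- mean(se, na.rm = TRUE)
  zo <- power_zero_one(p, cfg$alpha)
  se_est <- if (cfg$outcome == "quantitative")
    power_se(mg, mse, cfg$alpha, n_used = sum(conv)) else NULL

  out <- list(zero_one = zo, se_method = se_est,
              mean_gamma = mg, mean_se_gamma = mse,
              n_nonconverged = n_bad,
              unreliable = n_bad > 0.2 * cfg$iterations,
              panel = panel, hazard = hazard, cfg = cfg)
  if (keep_fits)
    out$fits <- data.frame(iter = seq_len(cfg$iterations), gamma = gamma,
                           se = se, p = p, converged = conv)
  class(out) <- "gbr_power"
  out
}

#' @export
print.gbr_power <- function(x, ...) {
  print(x$cfg)
  print(x$zero_one)
  if (!is.null(x$se_method))
    cat(sprintf("  SE-method cross-check: %.3f\n", x$se_method$power))
  if (x$n_nonconverged > 0)
    cat(sprintf("  non-converged fits dropped: %d%s\n", x$n_nonconverged,
                if (x$unreliable) " (UNRELIABLE: > 20%)" else ""))
  invisible(x)
}

# isotonic (non-decreasing) smoothing of evaluated (n, power) pairs;
# returns a function n -> smoothed power over the evaluated n's
smooth_power_curve <- function(n, power) {
  o <- order(n)
  ir <- isoreg(n[o], power[o])
  fitted <- ir$yf
  ns <- n[o]
  function(query) fitted[match(query, ns)]
}

#' Search for the minimum sample size reaching a target power
#'
#' Evaluates Monte-Carlo power on a coarse grid of trial sizes, smooths the
#' noisy power curve isotonically (power cannot truly decrease with n), and
#' bisects the bracketing interval down to `resolution` participants.
#' Returns the smallest evaluated n whose smoothed power reaches
#' `target_power`. Candidate sizes are snapped up to multiples of
#' `resolution`. Each candidate size gets its own seed derived from the
#' scenario seed, so the search path does not perturb individual estimates.
#'
#' @param cfg a [scenario_config()]; its `n_trial` is ignored.
#' @param target_power required power in (0, 1); a non-positive target
#'   returns the lower bracket end.
#' @param bracket integer interval of trial sizes to search; defaults to
#'   `c(50, frame_size)`.
#' @param grid_points number of geometric coarse-grid points.
#' @param resolution search resolution in participants (default 10; printed
#'   headline sizes usually carry "~" precision, so coarser values are
#'   reasonable and faster).
#' @param iterations Monte-Carlo iterations per evaluated size; defaults to
#'   the scenario's.
#' @param power_fn optional function `n -> power` replacing the Monte-Carlo
#'   evaluation (used for deterministic checks of the search itself).
#' @return An object of class `sample_size_search`: `n` (the crossing size,
#'   `NA` if unreachable), `power`, `mc_se`, `reached`, and `evaluations`
#'   (data frame of all evaluated sizes with raw and smoothed power).
#' @export
find_sample_size <- function(cfg, target_power = 0.8, bracket = NULL,
                             grid_points = 6, resolution = 10,
                             iterations = NULL, power_fn = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (target_power >= 1) stop_invalid_config("`target_power` must be below 1")
  if (is.null(bracket)) bracket <- c(50L, cfg$frame_size)
  check_interval(bracket, "bracket")
  if (bracket[2] > cfg$frame_size)
    stop_infeasible_design("bracket exceeds the sampling frame")
  resolution <- max(2L, as.integer(resolution))
  snap <- function(n) pmin(bracket[2],
                           pmax(bracket[1],
                                as.integer(ceiling(n / resolution) * resolution)))
  if (target_power <= 0) {
    return(structure(list(n = snap(bracket[1]), power = NA_real_,
                          mc_se = NA_real_, reached = TRUE,
                          evaluations = data.frame()),
                     class = "sample_size_search"))
  }
  iters <- if (is.null(iterations)) cfg$iterations else as.integer(iterations)
  evals <- data.frame(n = integer(0), power = numeric(0), mc_se = numeric(0))
  eval_at <- function(n) {
    hit <- match(n, evals$n)
    if (!is.na(hit)) return(invisible(NULL))
    if (!is.null(power_fn)) {
      pw <- power_fn(n); mc <- 0
    } else {
      cfg_n <- cfg
      cfg_n$n_trial <- as.integer(n)
      cfg_n$iterations <- iters
      cfg_n$seed <- derive_seed(cfg$seed, n)
      est <- estimate_power(cfg_n)
      pw <- est$zero_one$power; mc <- est$zero_one$mc_se
    }
    evals[nrow(evals) + 1L, ] <<- list(as.integer(n), pw, mc)
    invisible(NULL)
  }
  crossing <- function() {
    sm <- smooth_power_curve(evals$n, evals$power)
    ns <- sort(evals$n)
    ok <- sm(ns) >= target_power
    if (!any(ok)) return(NULL)
    hi <- ns[which(ok)[1]]
    below <- ns[ns < hi]
    list(lo = if (length(below)) max(below) else bracket[1], hi = hi,
         power = sm(hi))
  }

  grid <- unique(snap(exp(seq(log(bracket[1]), log(bracket[2]),
                              length.out = max(2, grid_points)))))
  for (n in grid) eval_at(n)
  cr <- crossing()
  if (is.null(cr)) {
    sm <- smooth_power_curve(evals$n, evals$power)
    best <- max(evals$n)
    return(structure(list(n = NA_integer_, power = sm(best),
                          mc_se = evals$mc_se[match(best, evals$n)],
                          reached = FALSE, evaluations = evals),
                     class = "sample_size_search"))
  }
  while (cr$hi - cr$lo > resolution) {
    mid <- snap((cr$lo + cr$hi) / 2)
    if (mid <= cr$lo || mid >= cr$hi) break
    eval_at(mid)
    cr <- crossing()
    if (is.null(cr)) break
  }
  if (is.null(cr)) { # smoothing pulled everything below target after refinement
    sm <- smooth_power_curve(evals$n, evals$power)
    best <- max(evals$n)
    return(structure(list(n = NA_integer_, power = sm(best),
                          mc_se = evals$mc_se[match(best, evals$n)],
                          reached = FALSE, evaluations = evals),
                     class = "sample_size_search"))
  }
  sm <- smooth_power_curve(evals$n, evals$power)
  evals$smoothed <- sm(evals$n)
  structure(list(n = cr$hi, power = cr$power,
                 mc_se = evals$mc_se[match(cr$hi, evals$n)],
                 reached = TRUE, evaluations = evals[order(evals$n), ]),
            class = "sample_size_search")
}

#' @export
print.sample_size_search <- function(x, ...) {
  if (x$reached)
    cat(sprintf("Minimum sample size: %d (smoothed power %.3f%s)\n", x$n, x$power,
                if (is.finite(x$mc_se)) sprintf(" +/- %.3f", x$mc_se) else ""))
  else
    cat(sprintf("Target power unreachable within the frame (best %.3f)\n", x$power))
  invisible(x)
}
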
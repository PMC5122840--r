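# Internal helpers: classed error conditions and seed derivation.

gbr_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "gbr_error"), call = call))
}

stop_invalid_config <- function(msg) gbr_stop(msg, "gbr_invalid_config")
stop_infeasible_design <- function(msg) gbr_stop(msg, "gbr_infeasible_design")
stop_infeasible_fit <- function(msg) gbr_stop(msg, "gbr_infeasible_fit")
stop_calibration_failure <- function(msg) gbr_stop(msg, "gbr_calibration_failure")
stop_degenerate_input <- function(msg) gbr_stop(msg, "gbr_degenerate_input")
stop_invalid_input <- function(msg) gbr_stop(msg, "gbr_invalid_input")

#' Derive a child RNG seed from a master seed and a counter
#'
#' Counter-based derivation keeps child streams independent of execution
#' order, so results for (say) each candidate sample size in a search are
#' reproducible in isolation. The derived seed always fits a 32-bit integer.
#'
#' @param master integer master seed.
#' @param counter non-negative integer counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, counter) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.double(master)) %% m)
  x <- (x * 48271 + 1) %% m
  x <- (x + (as.double(counter) %% m) * 69621) %% m
  x <- (x * 48271 + 1) %% m
  as.integer(x %% (m - 2) + 1)
}

check_interval <- function(x, name) {
  if (length(x) != 2 || anyNA(x) || !is.numeric(x) || x[1] > x[2])
    stop_invalid_config(sprintf("`%s` must be an ordered interval c(lo, hi)", name))
  invisible(x)
}
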
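# Scenario presets emulating the published Diabetes Prevention Program
# (DPP) interaction analyses, plus the four MAF-by-effect scenario families.

#' List the built-in scenario presets
#'
#' @return A data frame with one row per preset: name, outcome type and a
#'   short description.
#' @export
gbr_presets <- function() {
  data.frame(
    preset = c("dpp-metformin-slc47a1", "dpp-ili-grs32",
               "cox-high-large", "cox-high-small",
               "cox-moderate-large", "cox-moderate-small",
               "linear-high-large", "linear-high-small",
               "linear-moderate-large", "linear-moderate-small"),
    outcome = c("survival", "quantitative",
                rep("survival", 4), rep("quantitative", 4)),
    description = c(
      "Single SNP, MAF 0.44, metformin interaction HR 0.68, frame 31,000, 37% incidence over 4 y",
      "32-SNP GRS, lifestyle interaction -0.03 nmol/l per allele, frame 31,000",
      "20 SNPs, MAF 0.2-0.5, interaction |log-HR| 0.15-0.30, frame 10,000",
      "20 SNPs, MAF 0.2-0.5, interaction |log-HR| 0.05-0.15, frame 10,000",
      "20 SNPs, MAF 0.05-0.2, interaction |log-HR| 0.15-0.30, frame 10,000",
      "20 SNPs, MAF 0.05-0.2, interaction |log-HR| 0.05-0.15, frame 10,000",
      "20 SNPs, MAF 0.2-0.5, interaction 0.15-0.30 nmol/l decrease per allele, frame 10,000",
      "20 SNPs, MAF 0.2-0.5, interaction 0.05-0.15 nmol/l decrease per allele, frame 10,000",
      "20 SNPs, MAF 0.05-0.2, interaction 0.15-0.30 nmol/l decrease per allele, frame 10,000",
      "20 SNPs, MAF 0.05-0.2, interaction 0.05-0.15 nmol/l decrease per allele, frame 10,000"),
    stringsAsFactors = FALSE
  )
}

#' Build a scenario configuration from a preset
#'
#' Returns a [scenario_config()] pre-filled with the preset's genetic
#' architecture and outcome model; any argument of `scenario_config()`
#' (design, trial size, iteration count, seed, ...) can be overridden
#' through `...`.
#'
#' @param preset a preset name; see [gbr_presets()].
#' @param ... overrides passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
preset_config <- function(preset, ...) {
  over <- list(...)
  base <- switch(
    preset,
    "dpp-metformin-slc47a1" = list(
      outcome = "survival", frame_size = 31000, n_trial = 2155,
      freqs = 0.44, beta_int = log(0.68), beta_main = 0,
      followup = 4.0, target_incidence = 0.37),
    "dpp-ili-grs32" = list(
      outcome = "quantitative", frame_size = 31000, n_trial = 1900,
      k = 32, maf_range = c(0.05, 0.5), freqs = NULL,
      beta_int = NULL, effect_range = c(0.03, 0.03),
      direction = "protective", resid_sd = 1.0),
    "cox-high-large" = list(
      outcome = "survival", frame_size = 10000, k = 20,
      maf_range = c(0.2, 0.5), effect_range = c(0.15, 0.30)),
    "cox-high-small" = list(
      outcome = "survival", frame_size = 10000, k = 20,
      maf_range = c(0.2, 0.5), effect_range = c(0.05, 0.15)),
    "cox-moderate-large" = list(
      outcome = "survival", frame_size = 10000, k = 20,
      maf_range = c(0.05, 0.2), effect_range = c(0.15, 0.30)),
    "cox-moderate-small" = list(
      outcome = "survival", frame_size = 10000, k = 20,
      maf_range = c(0.05, 0.2), effect_range = c(0.05, 0.15)),
    "linear-high-large" = list(
      outcome = "quantitative", frame_size = 10000, k = 20,
      maf_range = c(0.2, 0.5), effect_range = c(0.15, 0.30), resid_sd = 1.0),
    "linear-high-small" = list(
      outcome = "quantitative", frame_size = 10000, k = 20,
      maf_range = c(0.2, 0.5), effect_range = c(0.05, 0.15), resid_sd = 1.0),
    "linear-moderate-large" = list(
      outcome = "quantitative", frame_size = 10000, k = 20,
      maf_range = c(0.05, 0.2), effect_range = c(0.15, 0.30), resid_sd = 1.0),
    "linear-moderate-small" = list(
      outcome = "quantitative", frame_size = 10000, k = 20,
      maf_range = c(0.05, 0.2), effect_range = c(0.05, 0.15), resid_sd = 1.0),
    stop_invalid_config(sprintf("unknown preset '%s'", preset))
  )
  args <- utils::modifyList(base, over)
  args$name <- if (is.null(over$name)) preset else over$name
  do.call(scenario_config, args)
}
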
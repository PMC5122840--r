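# Sampling frame construction, conventional and genotype-based recall
# recruitment, and 1:1 randomization.

#' Build a genotyped sampling frame
#'
#' Simulates `frame_size` individuals under Hardy-Weinberg equilibrium for
#' the panel's allele frequencies and precomputes every individual's
#' unweighted genetic risk score. The frame emulates a genotyped bioresource
#' from which trial participants are recruited.
#'
#' @param panel a [snp_panel].
#' @param frame_size number of genotyped individuals in the frame.
#' @return An object of class `sampling_frame` with elements `genotypes`,
#'   `grs` and `frame_size`.
#' @export
build_frame <- function(panel, frame_size) {
  if (frame_size < 2) stop_invalid_config("`frame_size` must be at least 2")
  g <- sample_genotypes(panel$freqs, frame_size)
  structure(
    list(genotypes = g, grs = compute_grs(g), frame_size = as.integer(frame_size)),
    class = "sampling_frame"
  )
}

#' @export
print.sampling_frame <- function(x, ...) {
  cat(sprintf("Sampling frame: %d individuals, %d SNPs\n",
              x$frame_size, ncol(x$genotypes)))
  cat(sprintf("  GRS: mean %.2f, range %d-%d\n",
              mean(x$grs), min(x$grs), max(x$grs)))
  invisible(x)
}

new_cohort <- function(frame, indices, tail) {
  idx <- as.integer(indices)
  structure(
    list(indices = idx,
         grs = frame$grs[idx],
         genotypes = frame$genotypes[idx, , drop = FALSE],
         tail = tail,
         arm = NULL,
         n = length(idx)),
    class = "trial_cohort"
  )
}

#' @export
print.trial_cohort <- function(x, ...) {
  cat(sprintf("Trial cohort: n = %d (%s)\n", x$n,
              if (all(x$tail == "na")) "conventional" else "genotype-based recall"))
  if (!is.null(x$arm))
    cat(sprintf("  arms: %d active / %d placebo\n", sum(x$arm == 1), sum(x$arm == 0)))
  invisible(x)
}

#' Conventional recruitment: simple random sampling from the frame
#'
#' Draws `n` individuals without replacement, ignoring genotype, so the
#' cohort GRS distribution is an unbiased draw from the frame's.
#'
#' @param frame a [build_frame()] result.
#' @param n trial size.
#' @return A `trial_cohort` (arms not yet assigned).
#' @export
recruit_conventional <- function(frame, n) {
  if (n < 1) stop_infeasible_design("trial size must be at least 1")
  if (n > frame$frame_size)
    stop_infeasible_design("trial size exceeds the sampling frame")
  idx <- sample.int(frame$frame_size, n)
  new_cohort(frame, idx, tail = rep("na", n))
}

#' Genotype-based recall from the GRS extremes
#'
#' Recruits from the most extreme point of each tail of the frame's GRS
#' distribution, working inwards towards the centre; no explicit cut-point
#' is used. The low tail receives `ceiling(n/2)` participants and the high
#' tail `floor(n/2)`. Ties at equal GRS are broken by frame index, so the
#' selection is deterministic given the frame. For a single-SNP design the
#' GRS is the allele count 0/1/2, so recall takes homozygotes first from
#' each end and moves to heterozygotes only when a tail is exhausted.
#'
#' @param frame a [build_frame()] result.
#' @param n trial size.
#' @return A `trial_cohort` with `tail` marking `"low"` or `"high"`.
#' @export
recruit_gbr <- function(frame, n) {
  if (n < 1) stop_infeasible_design("trial size must be at least 1")
  if (n > frame$frame_size)
    stop_infeasible_design("trial size exceeds the sampling frame")
  n_low <- ceiling(n / 2)
  n_high <- n - n_low
  ord <- order(frame$grs, seq_along(frame$grs)) # stable: ties by frame index
  low <- ord[seq_len(n_low)]
  high <- if (n_high > 0)
    ord[seq.int(frame$frame_size - n_high + 1L, frame$frame_size)]
  else integer(0)
  new_cohort(frame, c(low, high),
             tail = c(rep("low", n_low), rep("high", n_high)))
}

#' Randomize a cohort 1:1 to active treatment and placebo
#'
#' Permuted 1:1 allocation; arm sizes differ by at most one. For a
#' genotype-based recall cohort, allocation is stratified by tail so that
#' each tail is split 1:1 between arms, preventing chance confounding of
#' genetic extreme with treatment.
#'
#' @param cohort a `trial_cohort`.
#' @return The cohort with an `arm` element (1 = active, 0 = placebo).
#' @export
randomize_arms <- function(cohort) {
  if (cohort$n < 2) stop_invalid_config("cannot randomize fewer than 2 participants")
  arm <- integer(cohort$n)
  for (s in unique(cohort$tail)) {
    idx <- which(cohort$tail == s)
    arm[idx] <- sample(rep_len(c(1L, 0L), length(idx)))
  }
  cohort$arm <- arm
  cohort
}

#' Export a cohort as a data frame
#'
#' Columns `id` (frame row), `grs`, `tail` (`low`/`high`/`na`) and `arm`.
#'
#' @param cohort a `trial_cohort`.
#' @param path optional path; when given, written as a tab-separated file.
#' @return The data frame, invisibly when `path` is given.
#' @export
cohort_table <- function(cohort, path = NULL) {
  d <- data.frame(id = cohort$indices, grs = cohort$grs, tail = cohort$tail,
                  arm = if (is.null(cohort$arm)) NA_integer_ else cohort$arm)
  if (!is.null(path)) {
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(d))
  }
  d
}
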
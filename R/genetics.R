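# Genotype simulation under Hardy-Weinberg equilibrium and unweighted
# genetic risk scores.

#' Construct a SNP panel
#'
#' A SNP panel holds, for each locus, the effect-allele frequency, the
#' marginal (main) effect and the gene-by-treatment interaction effect.
#' Effects are on the log-hazard scale for survival outcomes and in outcome
#' units per allele for quantitative outcomes.
#'
#' @param freqs numeric vector of effect-allele frequencies, each strictly
#'   inside (0, 1).
#' @param beta_int per-allele interaction effects; recycled to the panel size.
#' @param beta_main per-allele marginal effects; recycled to the panel size.
#'   Defaults to 0, i.e. interaction-only data generation.
#' @param snp_id optional locus identifiers.
#' @return An object of class `snp_panel` with elements `freqs`, `beta_main`,
#'   `beta_int`, `k` and `snp_id`.
#' @export
snp_panel <- function(freqs, beta_int, beta_main = 0, snp_id = NULL) {
  freqs <- as.numeric(freqs)
  k <- length(freqs)
  if (k < 1) stop_invalid_config("a panel needs at least one SNP")
  if (anyNA(freqs) || any(freqs <= 0) || any(freqs >= 1))
    stop_invalid_config("allele frequencies must lie strictly in (0, 1)")
  beta_int <- rep_len(as.numeric(beta_int), k)
  beta_main <- rep_len(as.numeric(beta_main), k)
  if (anyNA(beta_int) || any(!is.finite(beta_int)) ||
      anyNA(beta_main) || any(!is.finite(beta_main)))
    stop_invalid_config("effect sizes must be finite")
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(k))
  structure(
    list(freqs = freqs, beta_main = beta_main, beta_int = beta_int,
         k = k, snp_id = as.character(snp_id)),
    class = "snp_panel"
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d loci\n", x$k))
  cat(sprintf("  effect-allele freq: %s\n",
              paste(format(range(x$freqs), digits = 3), collapse = " - ")))
  cat(sprintf("  interaction effects: %s\n",
              paste(format(range(x$beta_int), digits = 3), collapse = " - ")))
  invisible(x)
}

#' Draw a random SNP panel for a scenario family
#'
#' Frequencies are drawn uniformly within `maf_range`, and interaction
#' effect magnitudes uniformly within `effect_range`, independently across
#' loci. With `direction = "protective"` the interaction effects are made
#' negative (hazard ratio below 1, or a per-allele decrease in the outcome,
#' under active treatment). A panel is drawn once per scenario and then held
#' fixed across Monte-Carlo iterations: power is conditional on one
#' hypothesized genetic architecture.
#'
#' @param k number of SNPs.
#' @param maf_range interval of effect-allele frequencies, e.g. `c(0.2, 0.5)`.
#' @param effect_range interval of absolute per-allele interaction effects.
#' @param direction `"protective"` (negative effects under treatment) or
#'   `"adverse"`.
#' @param beta_main marginal per-allele effects; default 0 (see Details).
#' @return A [snp_panel].
#' @details The marginal effects default to zero so that the quantity under
#'   test, the interaction, is isolated; scenario configurations can
#'   override this.
#' @export
draw_panel <- function(k, maf_range, effect_range,
                       direction = c("protective", "adverse"),
                       beta_main = 0) {
  direction <- match.arg(direction)
  if (k < 1) stop_invalid_config("`k` must be at least 1")
  check_interval(maf_range, "maf_range")
  check_interval(effect_range, "effect_range")
  if (maf_range[1] <= 0 || maf_range[2] >= 1)
    stop_invalid_config("`maf_range` must lie strictly inside (0, 1)")
  freqs <- runif(k, maf_range[1], maf_range[2])
  mag <- runif(k, effect_range[1], effect_range[2])
  beta_int <- if (direction == "protective") -mag else mag
  snp_panel(freqs, beta_int = beta_int, beta_main = beta_main)
}

#' Read a SNP panel from a tab-separated file
#'
#' The file must have a header row with columns `snp_id`, `eaf`,
#' `beta_main`, `beta_int`.
#'
#' @param path file path.
#' @return A [snp_panel].
#' @export
read_panel <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "eaf", "beta_main", "beta_int")
  if (!all(need %in% names(d)))
    stop_invalid_config(paste("panel file must have columns:",
                              paste(need, collapse = ", ")))
  snp_panel(d$eaf, beta_int = d$beta_int, beta_main = d$beta_main,
            snp_id = d$snp_id)
}

#' Write a SNP panel to a tab-separated file
#'
#' @param panel a [snp_panel].
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  d <- data.frame(snp_id = panel$snp_id, eaf = panel$freqs,
                  beta_main = panel$beta_main, beta_int = panel$beta_int)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each entry of the returned matrix is an effect-allele count drawn as
#' Binomial(2, p_j), i.e. the sum of two independent allele draws, with
#' mutually independent columns (unlinked loci).
#'
#' @param freqs effect-allele frequencies, each strictly in (0, 1).
#' @param n number of individuals.
#' @return An `n x k` integer matrix with entries in \{0, 1, 2\}.
#' @export
sample_genotypes <- function(freqs, n) {
  if (n < 1) stop_invalid_config("`n` must be at least 1")
  if (anyNA(freqs) || any(freqs <= 0) || any(freqs >= 1))
    stop_invalid_config("allele frequencies must lie strictly in (0, 1)")
  k <- length(freqs)
  g <- rbinom(n * k, size = 2L, prob = rep(freqs, each = n))
  matrix(as.numeric(g), nrow = n, ncol = k)
}

#' Unweighted genetic risk score
#'
#' Per-individual sum of effect-allele counts across the panel. For a panel
#' of k SNPs the theoretical range is 0 to 2k.
#'
#' @param genotypes genotype matrix from [sample_genotypes()].
#' @return Numeric vector of integer-valued scores.
#' @export
compute_grs <- function(genotypes) {
  if (is.null(dim(genotypes)) || nrow(genotypes) < 1 || ncol(genotypes) < 1)
    stop_invalid_input("`genotypes` must be a non-empty matrix")
  rowSums(genotypes)
}
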
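---
title: "Simulating power for genotype-based recall trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating power for genotype-based recall trials: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Randomized controlled trials (RCTs) that test whether a treatment effect is
modified by genotype — a gene-by-treatment interaction — are usually
underpowered: interaction contrasts carry roughly a quarter of the
information of a main-effect contrast of the same magnitude, and per-allele
interaction effects for complex traits are small. One remedy is
*genotype-based recall* (GBR): instead of recruiting trial participants at
random and genotyping them afterwards, participants are recalled from a
pre-genotyped sampling frame (a bioresource such as a population cohort or
biobank) by their genotype, specifically from the two extremes of a genetic
risk score (GRS) distribution. Juxtaposing many-allele and few-allele
carriers maximizes the genetic contrast inside the trial, and therefore the
information available for the interaction test, at a fixed trial size.

`gbrpower` is a seeded Monte-Carlo simulator that quantifies this gain. It
estimates statistical power and minimum sample size for gene-by-treatment
interaction tests under the two recruitment paradigms, for two outcome
families:

* **time-to-event** outcomes (e.g. incident type 2 diabetes), analysed with
  a Cox proportional hazards model, and
* **quantitative** outcomes (e.g. 1-year change in small LDL particle
  concentration), analysed with linear regression,

with optional classical measurement error on the quantitative outcome.

## Generative model

### Genotypes and risk scores

Each scenario fixes a panel of `k` unlinked SNPs with effect-allele
frequencies `p_j` and per-allele effects. Genotypes are drawn under
Hardy-Weinberg equilibrium: the allele count for SNP `j` is
Binomial(2, `p_j`), independently across loci and individuals. The GRS is
the unweighted sum of effect-allele counts, with range `0..2k`, mean
`sum(2 p_j)` and variance `sum(2 p_j (1 - p_j))`. For the panels used here
(20 SNPs, frequencies 0.2–0.5) the GRS is close to normal (analytic
skewness 0.094 for a panel spanning that range; the test suite checks the
simulated value).

A scenario's panel is drawn **once** from the scenario seed and reused
across all Monte-Carlo iterations: power is conditional on one hypothesized
genetic architecture, exactly as a real GBR trial is designed around one
pre-specified score. Frame genotypes, by contrast, are re-simulated every
iteration, so the Monte-Carlo error reflects both frame and trial sampling.

### Recruitment and randomization

* *Conventional*: a simple random sample of `n` from the frame.
* *GBR*: the `ceiling(n/2)` lowest-GRS and `floor(n/2)` highest-GRS frame
  members — recruitment starts at the most extreme point of each tail and
  works inwards, with no explicit cut-point. Ties at equal GRS are broken
  by frame index so the selection is deterministic; with an odd `n` the
  extra participant goes to the low tail (an arbitrary but fixed rule). In
  a single-SNP design the GRS is the allele count, so GBR recruits
  homozygotes first and moves to heterozygotes only when a tail is
  exhausted, equilibrating the allele frequency inside the trial.

Randomization is permuted 1:1; for GBR cohorts it is stratified by tail so
that chance cannot confound genetic extreme with treatment arm. The
published description is silent on stratification; we stratify because it
matches RCT practice and removes a nuisance source of Monte-Carlo noise.

### Survival outcomes

Event times come from the inverse cumulative-hazard transform for a
proportional hazards model: with `U ~ Uniform(0, 1)`,

    T = -log(U) / (lambda0 * exp(eta)),
    eta = treatment_main * arm + G beta_main + (G beta_int) * arm,

where `G` is the participant's genotype row. The baseline hazard is
exponential (constant `lambda0`). The abstract inverse-baseline-hazard
formulation admits any monotone cumulative hazard; we use the exponential
because it is the canonical choice for this transform, has a closed-form
inverse, and is exactly identified by the single calibration constraint
below. Follow-up is administratively censored at `followup` years (default
4.0): a participant whose latent time reaches the horizon is censored, and
no dropout or competing risk is modelled.

`lambda0` is calibrated so the *population* event fraction at end of
follow-up equals `target_incidence` (default 37% at 4 years, the reference
trial's approximate overall diabetes incidence):

    mean_i [ 1 - exp(-lambda0 * followup * exp(eta_i)) ] = target_incidence,

with treatment marginalized as a fair coin and the mean taken over a
calibration frame's covariates. Calibration is done once per scenario —
incidence is a property of the population, not of a recruited cohort, so a
GBR cohort's realized event fraction may legitimately differ. The equation
is solved by bracketed root-finding on `log(lambda0)` to a relative
tolerance of 1e-8; the calibration frame is capped at 100,000 rows, which
makes the Monte-Carlo error of the calibrated rate negligible relative to
that tolerance.

### Quantitative outcomes

    y = treatment_main * arm + G beta_main + (G beta_int) * arm + e,
    e ~ Normal(0, resid_sd^2).

Measurement error, when requested, is classical and additive on the
outcome only: `y_obs = y_true + Normal(0, sigma_e^2)` with
`sigma_e^2 = Var(y_true) (1 - r2) / r2`, so the squared correlation
between observed and true outcome is `r2` (0.8 / 0.6 / 0.4 for high /
moderate / low assessment precision). Error on the genotype side (e.g.
recalling on a proxy variant in imperfect LD with the functional one) is
out of scope.

## Analysis model and power

Each simulated trial is analysed exactly as a real one would be: a Cox
model (Breslow tie handling) or OLS regression of the outcome on
`{GRS, arm, GRS x arm}`, and the two-sided Wald test of the interaction
coefficient `gamma`. Data are *generated* per SNP but *analysed* through
the aggregate GRS; this generation/analysis mismatch is intentional and
mirrors practice. Continuous simulated times make ties measure-zero, so
the tie method is inconsequential but fixed. Fits with no event in an arm,
zero cohort GRS variance, non-convergence or a monotone likelihood
(separation) are flagged and dropped from both numerator and denominator
of power; their count is reported and an estimate with more than 20%
dropped is flagged unreliable.

Power is estimated two ways:

* **Zero/One**: the fraction of converged iterations with `p < alpha`
  (strict inequality), with binomial Monte-Carlo standard error. This is
  the primary estimator for both model families.
* **Standard-Error** (quantitative outcomes, as a cross-check):
  `Phi(|mean(gamma)| / mean(SE) - z_{1 - alpha/2})`, where the fitted
  effects and standard errors are averaged separately across iterations
  and then ratioed — the literal reading of the published description.
  The suite checks the two estimators agree within 0.02 at 1,000
  iterations.

The minimum sample size for a target power is found by evaluating power on
a coarse geometric grid of trial sizes, smoothing the noisy Monte-Carlo
power curve isotonically (true power cannot decrease with `n`), and
bisecting the bracketing interval; candidate sizes are snapped to
multiples of the search resolution (default 10 participants; the headline
analyses use 50, matching the "~" precision with which such sizes are
usually quoted). Every candidate size gets its own seed derived from the
scenario seed by a counter scheme, so results are independent of the
search path and of execution order.

## Tunable parameters

| parameter | units | default | notes |
|---|---|---|---|
| `k`, `maf_range` | — | 20, (0.2, 0.5) | panel size and frequency range; "moderate" frequency is (0.05, 0.2) |
| `effect_range` | log-HR or outcome units per allele | (0.15, 0.30) | interaction magnitudes; "small" is (0.05, 0.15); `direction = "protective"` makes them negative |
| `beta_main` | log-HR or outcome units per allele | 0 | marginal SNP effects; zero isolates the interaction, the quantity under test |
| `treatment_main` | log-HR or outcome units | 0 | treatment main effect |
| `followup` | years | 4.0 | administrative censoring horizon |
| `target_incidence` | proportion | 0.37 | overall event fraction the baseline hazard is calibrated to |
| `resid_sd` | outcome units | 1.0 | residual SD of the quantitative outcome |
| `r2_error` | proportion | 1.0 | outcome reliability; 1 disables measurement error |
| `alpha` | — | 0.05 | two-sided significance level of the interaction Wald test |
| `iterations` | — | 1000 | Monte-Carlo iterations per power estimate |

The source publications never state the marginal SNP effects, the
treatment main effect, or the residual SD of the quantitative outcome, so
these default to the most reproducible null choices (0, 0, 1.0) and are
exposed as configuration knobs. Because absolute quantitative power scales
with `beta_int / resid_sd`, printed sample sizes for the linear scenarios
are reproducible only up to that unknown scale; the package's checks for
those scenarios are therefore structural (orderings, equivalences) rather
than absolute.

## What the simulator does and does not emulate

The generator emulates: HWE genotypes at unlinked loci, extreme-tail
recall from a finite genotyped frame, 1:1 (tail-stratified) allocation,
proportional-hazards event times with administrative censoring,
linear-in-allele-count effects, and classical outcome measurement error.

It does **not** emulate: linkage disequilibrium or recall on proxy
variants, eligibility screening (in the reference trial only ~10% of the
~31,000 screened were eligible — a real GBR trial would need a
correspondingly larger frame), genotype-associated retention, staggered
entry or interval-censored detection at scheduled visits, competing risks,
weighted risk scores, or non-linear (threshold) interaction across the
GRS distribution. Passing tests therefore demonstrate the statistical
behaviour of the idealized design, not the operational feasibility of a
specific trial.

## Numerical and design choices

* Exponential baseline hazard; a Weibull extension would only require
  replacing the inverse cumulative hazard and its calibration.
* Calibration by `uniroot` on the log scale, bracket `[1e-10, 1e6]` per
  year; no sign change raises a calibration-failure error.
* Separation guard for the Cox fit: |coefficient| > 15, SE > 50 or hitting
  the iteration cap flags the fit as non-converged rather than returning a
  spurious astronomically-significant result.
* The Zero/One threshold is strict (`p < alpha`): a p-value exactly at the
  threshold counts as a failure.
* Isotonic smoothing before thresholding the power curve guarantees the
  reported sample size is monotone-consistent with all evaluations made.
* Seeds: one master seed per scenario; iteration seeds, panel seed,
  calibration seed and per-candidate-size seeds are derived by a
  counter-based map into [1, 2^31 - 2], so any subset of the computation
  is reproducible in isolation and results do not depend on execution
  order or parallel scheduling.

## Problem sizes used in the shipped checks

The package's own verification uses: 1,000 iterations for the reference
single-SNP power estimate and the Zero/One-vs-Standard-Error comparison;
200–300 iterations per evaluated size in sample-size searches at
resolution 50; 2,000 trials per cell for type-I error calibration
(frame 3,000, trial 400, five null SNPs); 60 replicates of exhaustive
50,000-participant cohorts for effect-recovery checks; and 250-iteration
estimates for the design/frame-size/measurement-error orderings. These
sizes give binomial Monte-Carlo standard errors of 0.5–3 percentage
points on power, adequate for the tolerances being checked.

## Known limitations

* Power for GBR designs is conditional on the frame actually containing
  enough extreme-GRS individuals; with very small frames or very rare
  alleles the tails meet the middle and the GBR advantage dissolves (the
  simulator reproduces this: conventional power is frame-size invariant
  while GBR power grows with the frame).
* Non-convergence is frequent at very small trial sizes (few events per
  arm), where the power estimate is flagged unreliable rather than
  silently reported.
* The linear-model absolute power depends on the unknown residual SD, as
  discussed above.
* A published figure obtained under nuisance-parameter choices that are
  not stated (e.g. an empirically estimated interaction standard error
  rather than a fully specified generative model) cannot be reproduced
  exactly by any generative simulator, this one included; the package
  reports what its stated model implies.
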
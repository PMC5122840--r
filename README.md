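# gbrpower

Monte-Carlo power and sample-size calculations for randomized controlled
trials that test **gene-by-treatment interactions**, comparing two
recruitment paradigms:

* **conventional sampling** — participants are drawn at random from a
  genotyped sampling frame (a bioresource or screening population) without
  regard to genotype;
* **genotype-based recall (GBR)** — participants are recalled from the two
  extremes of the frame's genetic risk score (GRS) distribution, working
  inwards from the most extreme individuals, which maximizes the genetic
  contrast (and hence the interaction information) inside the trial.

The package is aimed at statisticians and genetic epidemiologists designing
recall trials around an existing genotyped cohort, and at anyone who wants
to quantify how much smaller a GBR trial can be than a conventional one for
the same interaction hypothesis.

## Model

Genotypes are simulated under Hardy-Weinberg equilibrium (allele count
`g_ij ~ Binomial(2, p_j)`, unlinked loci) and aggregated into an unweighted
GRS `G_i = sum_j g_ij`. For time-to-event outcomes, event times follow a
proportional-hazards model via the inverse cumulative-hazard transform

    T_i = -log(U_i) / (lambda0 * exp(eta_i)),   U_i ~ Uniform(0, 1)
    eta_i = beta_trt * arm_i + sum_j beta_main_j g_ij + sum_j beta_int_j g_ij arm_i

with exponential baseline rate `lambda0` calibrated so the population event
fraction at the end of follow-up matches a target incidence (default 37% at
4 years), and administrative censoring at the follow-up horizon. Each
simulated trial is analysed with a Cox model of `Surv(T, event)` on
`{G, arm, G x arm}` (Breslow ties). Quantitative outcomes use the analogous
linear model with Gaussian residuals, analysed by OLS, optionally after
adding classical measurement error tuned to a reliability `r2`.

Power for the interaction coefficient `gamma` is the fraction of simulated
trials with a two-sided Wald `p < alpha` (the *Zero/One* method); for
linear models the analytic *Standard-Error* method
`Phi(|mean gamma| / mean SE - z_{1-alpha/2})` is computed as a cross-check.
The minimum `n` reaching a target power is found by a coarse grid plus
bisection on an isotonically smoothed power curve.

## Worked example

Power to detect a per-allele interaction hazard ratio of 0.68 between a
single variant (effect-allele frequency 0.44) and treatment, in a trial of
1,000 participants recruited from a 31,000-person frame, with 37% overall
incidence over 4 years — the metformin-pharmacogenetics preset:

```r
library(gbrpower)

cfg <- preset_config("dpp-metformin-slc47a1", design = "conventional",
                     n_trial = 1000, iterations = 300, seed = 2024)
estimate_power(cfg)
#> Scenario 'dpp-metformin-slc47a1': conventional recruitment, survival outcome
#>   frame 31000, trial n 1000, alpha 0.05, 300 iterations, seed 2024
#> Power (zero_one method): 0.733 +/- 0.026 (MC SE) [300 simulations]

cfg_gbr <- preset_config("dpp-metformin-slc47a1", design = "gbr",
                         n_trial = 1000, iterations = 300, seed = 2024)
estimate_power(cfg_gbr)
#> Scenario 'dpp-metformin-slc47a1': gbr recruitment, survival outcome
#>   frame 31000, trial n 1000, alpha 0.05, 300 iterations, seed 2024
#> Power (zero_one method): 0.947 +/- 0.013 (MC SE) [300 simulations]
```

Reading: at the same trial size, recalling the extreme genotype groups
(here, homozygote carriers versus homozygote non-carriers) raises power
from 73% to 95%; the `+/-` figures are binomial Monte-Carlo standard
errors over the 300 simulated trials. `find_sample_size(cfg, 0.8)` inverts
the power curve to report the smallest trial reaching 80% power, and
`gbr_presets()` lists the built-in scenario presets (single-SNP
pharmacogenetic, 32-SNP lifestyle-intervention, and the four
frequency-by-effect-size scenario families).

A YAML-driven front end covers batch use:

```sh
inst/cli/gbr-power run  -c config.yaml -o outdir   # power curves / searches
inst/cli/gbr-power grid -c grid.yaml   -o outdir   # design x MAF x effect grids
inst/cli/gbr-power presets                         # list presets
```

Outputs are tab-separated (`power_curve.tsv`, `sample_size.tsv`,
`grid_results.tsv`) plus a `manifest.json` that echoes the configuration
and master seed; re-running an identical configuration reproduces every
output bit-for-bit.

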
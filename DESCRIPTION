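Package: gbrpower
Title: Power and Sample Size Simulation for Genotype-Based Recall Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded Monte-Carlo simulation of statistical power and minimum
    sample size for gene-by-treatment interaction tests in randomized
    controlled trials. Compares conventional random recruitment with
    genotype-based recall (GBR), where participants are recalled from the two
    extremes of a genetic risk score distribution in a genotyped sampling
    frame. Supports time-to-event outcomes simulated by inverse-cumulative-
    hazard transformation and analysed with Cox proportional hazards models,
    and quantitative outcomes analysed by linear regression, with optional
    classical measurement error on the outcome. Includes presets emulating
    published Diabetes Prevention Program interaction analyses, a scenario
    grid runner, and a sample-size search with isotonic smoothing of the
    Monte-Carlo power curve.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
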
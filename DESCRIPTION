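Package: screensig
Title: Hit Calling for Arrayed Expression Screens and Gene-Signature
    Activation Scoring in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical analysis of arrayed perturbation
    screens read out by probe-level molecular counting (NanoString-style),
    and for downstream gene-signature work. Normalizes probe counts with
    positive spike-in and housekeeping controls, calls illegitimate-induction
    hits per probe/perturbation pair with per-probe Z-scores at configurable
    sigma thresholds, derives an inhibitor-dependence gene signature from a
    three-condition expression experiment, and scores signature activation in
    tumor cohorts against a random-signature resampling null with a Gumbel
    tail approximation. Includes seeded synthetic-data generators with known
    ground truth for every stage, broom-style tidiers, and ggplot2 autoplot
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
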
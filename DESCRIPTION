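Package: psymediate
Title: Moderated Multilevel Mediation for Psychophysics Trial Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing stimulus-perception-behavior relationships
    in trial-level psychophysics experiments with pain and touch stimuli.
    Implements trial-level preprocessing (misidentification, zero-rating and
    reaction-time outlier exclusion; intensity centering; stratified
    z-scoring), moderated multilevel mediation with quasi-Bayesian Monte
    Carlo inference (mediation and direct effects per stimulus modality,
    percentile confidence intervals, modality-difference p values,
    back-transformation to original units), subject-level permutation tests
    for group differences in the proportion mediated, mixed between-within
    repeated-measures ANOVAs, and a synthetic trial generator that emulates
    the two-group, two-modality, three-intensity paradigm so that every
    stage of the pipeline can be exercised and power-analysed without
    access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
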
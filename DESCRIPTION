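Package: pubtiming
Title: Indicator-Based Pubertal Timing from Longitudinal Growth and
    Development Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives and compares indicator-based measures of pubertal
    timing from longitudinal anthropometric and pubertal-development data.
    Fits SITAR (SuperImposition by Translation And Rotation)
    shape-invariant nonlinear mixed-effects growth models in three
    variants (three random effects for height; four including a
    post-growth slope for weight and bone mineral content; a reduced
    two-effect model for ordinal Tanner-type scales), extracts population
    landmarks (age at peak velocity, stage-crossing ages) and
    individual-level pubertal ages from the timing random effects, and
    runs the downstream analyses: timing and sequence summaries, pairwise
    Pearson correlations, genetic risk score construction and association,
    and confounder-adjusted body-composition regressions. Includes a
    synthetic-cohort generator with known ground truth for validating the
    whole pipeline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nlme,
    splines,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
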
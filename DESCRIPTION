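Package: retinomapper
Title: Fourier Retinotopy and Visual Area Quantification for Widefield
    Intrinsic Signal Imaging
Version: 0.1.0
Authors@R:
    person("retinomapper", "developers", email = "retinomapper@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for phase-encoded retinotopic mapping of mouse
    visual cortex with widefield intrinsic signal optical imaging (ISOI).
    Reads multi-page TIFF movie stacks with JSON metadata sidecars, performs
    4x temporal and 2x2 spatial binning, extracts per-pixel magnitude and
    phase at the stimulus frequency, converts phase to azimuth and elevation
    retinotopy, segments V1 and higher visual areas by visual field sign
    reversals, quantifies V1-normalized response amplitudes within a
    responsive-cortex mask, and runs one-way and two-way ANOVA with
    Bonferroni post hoc tests. Includes a forward simulator of synthetic
    ISOI movies and cohorts with known ground truth for parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
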
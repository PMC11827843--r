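Package: screenkit
Title: Pooled CRISPR Dropout Screen Scoring with NTC-Resampled NormZ and HSA Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for pooled CRISPR/Cas9 knockout dropout screens
    run with and without drug treatment. Computes guide-level fold-change
    z-scores with a rank-window empirical-Bayes variance estimate and
    gene-level normalized z (normZ) statistics with one-tailed p-values and
    Benjamini-Hochberg false discovery rates; wraps the scorer in a
    resampling scheme that aggregates non-targeting control guides into
    random pseudogenes and averages scores over repetitions; nominates
    drug-sensitizer hits from paired fitness and drug contrasts; and scores
    two-drug dose-response matrices with the highest-single-agent (HSA)
    synergy model. Includes a seeded synthetic screen generator with known
    truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
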
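Package: tauseedr
Title: Simulated Live-Imaging Analysis of Seeded Tau Aggregation and
    Neuronal Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse two-channel time-lapse imaging
    of iPSC-derived neurons expressing a seeding-competent TauRD-YFP
    reporter together with a far-red vital nuclear dye. Includes a
    ground-truthed synthetic microscopy generator (per-cell aggregation
    onset, death and field-exit hazards, aggregate morphology archetypes,
    nuclear lysis flash), punctum and soma-aggregate detection with
    local-background thresholding, greedy nearest-neighbour single-cell
    tracking with censoring, Kaplan-Meier / log-rank / Cox survival
    statistics on seed-addition and post-onset clocks, seeding-curve
    analytics (baseline subtraction, AUC, dose ANOVA, early slopes), and
    rule-based aggregate-morphology classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    survival,
    car,
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
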
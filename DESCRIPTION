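Package: alcslope
Title: Lymphocyte Depletion Kinetics and Aggressive-Course Survival Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a per-patient exponential decay slope from serial
    absolute lymphocyte counts (ALC) measured during concurrent
    chemoradiotherapy, by constrained least squares profiled over a dense
    grid of decay rates with a top-candidate selection rule. Builds
    disease-specific survival endpoints that separate aggressive (early)
    from non-aggressive (late) cancer deaths, and provides Kaplan-Meier,
    log-rank, and AIC-backward-elimination Cox analyses stratified by the
    slope and the neutrophil-to-lymphocyte ratio. A companion arm computes
    paired log2 fold changes from exosomal mRNA read counts after TMM
    normalization, screens genes against the slope and outcomes, and
    searches gene subsets for composite risk scores. A synthetic cohort
    generator reproduces the statistical structure of such studies so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
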
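Package: rvotep
Title: Action Potential Features, Arrhythmia Detection and Fibrosis
    Quantification for Paced Myocardial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo electrophysiology of right
    ventricular outflow tract myocardium. Segments paced intracellular
    membrane-potential recordings into action potentials, applies quality
    control, and computes shape properties (resting membrane potential,
    amplitude, maximum upstroke velocity, APD20/50/90, AUC90). Detects
    pro-arrhythmic tissue abnormalities (early afterdepolarisations,
    extrasystoles, spontaneous couplets, APD alternans, impaired
    rate-adaptation with 2:1 capture failure). Quantifies percent-fibrosis
    from picrosirius-red-stained section images with exclusion of
    background, tissue gaps and thickened endocardium. Fits linear
    mixed-effects association models with a per-patient random intercept,
    binomial logistic regressions and two-sample t-tests. Includes
    synthetic-data generators with analytically known ground truth for
    recordings, histology sections and cohort feature tables, so the whole
    pipeline is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    lme4,
    lmerTest,
    jsonlite,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
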
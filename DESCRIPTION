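Package: lunghet
Title: Lung Heterogeneity from Inspired Sinewave Tests and Quantitative CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bedside and imaging-based quantification of ventilation
    and perfusion heterogeneity in the injured lung. Implements a
    multi-compartment tidal-breathing simulator of an inert tracer gas under
    sinusoidal inspired forcing, recovery of effective lung volume, pulmonary
    blood flow and deadspace from per-breath tracer traces, two heterogeneity
    indices (the two-period ratio method and simulation-fitted log-normal
    spreads of specific ventilation and perfusion), quantitative CT analysis
    (Hounsfield-unit aeration compartments, gas/tissue mass decomposition and
    a voxel-ring inhomogeneity index), and the comparison statistics linking
    the two modalities (correlation matrices, per-animal regression and
    four-quadrant trend concordance). A synthetic porcine lavage-injury cohort
    generator provides end-to-end validation without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
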
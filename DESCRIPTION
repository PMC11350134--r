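Package: centistress
Title: Stress Testing Centiloid Quantification of Amyloid PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation and statistics toolkit for assessing the bias and
    precision of Centiloid (CL) quantification of amyloid PET. Provides a
    voxelised digital brain phantom with tracer-specific uptake, age-dependent
    white-matter binding, global grey-matter atrophy, and point-spread
    smoothing with 8 mm harmonisation; a factorial engine of 32 Centiloid
    quantification pipelines (reference region, mask provenance, target
    definition, quantification space); anchor-based and level-2 tracer
    calibration with standard validation criteria; generalized estimating
    equations with Type III Wald tests and marginal means for the bias models;
    and within/between-pipeline variance decomposition, confidence-interval
    interpolation at amyloid-positivity cutoffs, ICC(2,1) and Bland-Altman
    agreement for the precision analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
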
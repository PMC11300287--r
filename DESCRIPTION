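Package: cshdwi
Title: Consumption-and-Supply Hypoxia Mapping from Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates tumor hypoxia from multi-b-value diffusion-weighted MRI
    using the Consumption-and-Supply Hypoxia (CSH) model. Provides segmented
    intravoxel incoherent motion (IVIM) fitting of apparent diffusion
    coefficient (ADC) and fractional blood volume (fBV) maps, voxel-level
    hypoxia classification and lesion-level hypoxia fractions, cross-cohort
    calibration by propensity-score optimal matching and median scaling,
    assumption-gated group-comparison statistics, and a synthetic two-center
    cohort generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
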
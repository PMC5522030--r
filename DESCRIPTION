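Package: qsarch
Title: Tumor Architecture from Generalized Q-Space Imaging Tractography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intra-tumor architecture from multi-direction
    diffusion-weighted MRI. Reconstructs per-voxel spin distribution
    functions with the generalized Q-space imaging (GQI) sinc-kernel
    summation, runs deterministic streamline tractography with an angular
    threshold, and summarizes the resulting tract-length field as
    core/shell populations (the c/s ratio), concentric-ring radial
    profiles and a two-component Gaussian tract-length mixture. Couples
    architecture metrics to outcome through Kaplan-Meier estimation,
    log-rank testing, hazard ratios and Cox proportional-hazards models.
    Includes generators for core-shell diffusion phantoms with Rician
    noise and for synthetic survival cohorts with a configurable
    c/s-ratio effect, so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
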
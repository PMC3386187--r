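Package: ilpcitex
Title: Texture Analysis of In-Line Phase-Contrast Liver Tumor Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and texture analysis pipeline for propagation-based
    (in-line) X-ray phase-contrast projection images of liver tissue bearing
    staged hepatic tumors. Generates ground-truthed synthetic projections via
    a paraxial Fresnel forward model with a weak-object transport-of-intensity
    approximation and a detector model; samples fixed-size regions of interest
    inside labeled tissue regions; computes gray-level co-occurrence matrices
    and nine Haralick texture parameters; decomposes patches with a two-level
    dual-tree complex wavelet transform and re-extracts subband texture;
    discriminates normal from tumor regions by the sign of the first principal
    component of standardized texture features; and classifies tumor stage
    from low-frequency subband texture with a cross-validated support vector
    machine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
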
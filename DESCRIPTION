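Package: myoconduct
Title: Image-Based Estimation of Intracellular Conductivity Tensors in Myocardium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates anisotropic intracellular electrical conductivity
    tensors of cardiac tissue from 3D labeled voxel reconstructions.
    Derives gap-junction-containing voxels from a connexin43 channel,
    calibrates their conductivity against a reference myocyte-pair
    conductance, builds piecewise-constant conductivity models, solves
    Poisson's equation for stationary currents under electrode boundary
    conditions with a flux-conservative finite-volume scheme, and extracts
    directional (longitudinal, transverse, sheet-normal) conductivities.
    Includes a synthetic brick-myocyte tissue generator with closed-form
    conductivity references, tissue-composition and orientation features
    with quality-control exclusion rules, and the regression and group
    comparison statistics used to relate microstructure to conductivity.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
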
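Package: mitomorph3d
Title: Quantitative 3D Mitochondrial Morphometry from Labeled Electron Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-organelle morphometry of mitochondria segmented from serial
    block face scanning electron microscopy (SBF-SEM) volumes. Extracts
    individual organelles from integer-labeled anisotropic voxel stacks,
    meshes them, and computes surface area, volume, the mitochondrial
    complexity index (MCI), sphericity, and the mitochondrial branching
    index (MBI). Detects and measures mitochondrial nanotunnels
    (length, external diameter extremes, estimated matrix lumen).
    Provides population-level analytics (percentile-based simple/complex
    and small/large classes, multi-level coefficients of variation,
    volume density, distribution shape), nested random-effect variance
    decomposition, and a PLS-DA morphological signature with variable
    importance in projection (VIP) scores. Includes a synthetic phantom
    and cohort generator with analytic ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    lme4,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
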
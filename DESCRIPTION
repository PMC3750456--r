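Package: orbitqc
Title: Quality Control of Orbital Reconstruction by Volumetry and
    Mirror-Template Shape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the quality of post-traumatic orbital wall
    reconstruction from volumetric head imaging (CT/CBCT). Implements
    landmark-clipped segmentation and voxel-count volumetry of the bony
    orbital cavity, construction of a mirror template from the unaffected
    side, ROI-restricted rigid surface registration (trimmed point-to-plane
    ICP), signed minimal-perpendicular-distance deviation mapping over a
    nine-region anatomical partition of the orbital walls, titanium-implant
    coverage analysis, and cohort-level volume statistics. Ships a synthetic
    orbit phantom generator with full ground truth so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
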
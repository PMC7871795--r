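Package: sulcalpits
Title: Sulcal Pits Morphometry on Cortical Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extraction and group analysis of sulcal pits, the locally
    deepest points of cortical folds, on triangle meshes of the white
    matter surface. Implements per-vertex depth estimation with the depth
    potential function, a filtered watershed with ridge-height, geodesic
    distance and area merging rules and brain-size threshold
    normalization, group-level density parcellation, depth-based
    classification of folds into primary sulci, secondary sulci and
    dimples, and the group-difference, age and hemispheric-asymmetry
    statistics built on those measurements. Includes a synthetic
    folded-surface cohort generator so every stage is testable without
    imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
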
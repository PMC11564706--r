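Package: mammoplan
Title: Surgical-Planning Morphometry for 3D Breast MRI Label Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of multi-tissue 3D label maps segmented from
    breast dynamic contrast-enhanced MRI. Implements automated surgical-planning
    metrics: nipple localization from tissue adjacency, breast-box construction
    from five skin-anchored key points, axis-aligned tumor dimensions and
    volumes, vertex-set tumor-to-landmark distances, tissue-balanced breast
    quadrant localization, and unicentric/multicentric convex margin hulls with
    overlap merging. Also provides segmentation-evaluation statistics (Dice,
    Hausdorff) and reader-agreement statistics (concordance, Gwet's AC1,
    Clopper-Pearson exact lower bound), plus a deterministic digital breast
    phantom generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    RANN,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
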
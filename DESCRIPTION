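Package: pamorph
Title: Automated Morphometry of Pulmonary-Artery Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Centreline-based morphometry of pulmonary-artery-like vascular
    trees. Generates parametric synthetic vessel trees with analytically known
    geometry, reconstructs triangulated surfaces from binary voxel masks
    (marching-tetrahedra extraction and volume-preserving smoothing), extracts
    rooted centreline trees with maximal-inscribed-sphere radii, labels the
    main, left, and right pulmonary artery and their side branches, and
    computes the geometric size and shape parameters used to characterise
    candidate device landing zones: branch lengths, length-weighted diameters,
    taper, curvature index, enlargement index, and the bifurcation angle.
    Includes surface-distance comparison of independent reconstructions and
    cohort-level statistics (normality-gated descriptives and tests,
    Bland-Altman limits of agreement, ICC(1,1), and a coded cross-species
    similarity table).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    xml2,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
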
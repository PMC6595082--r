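Package: longivol
Title: Registration-Agnostic Longitudinal Structure Volumetry and Atrophy Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures longitudinal volume change of compact brain structures
    (hippocampus-scale) from binary segmentations and dense displacement
    fields produced by any non-linear registration tool.  Binary masks are
    converted to closed triangle meshes by marching cubes, meshes are
    propagated through affine transforms or displacement fields without
    resampling, and volumes are computed as sums of signed tetrahedra; an
    independent Jacobian-determinant integration route cross-checks every
    mesh-based measurement.  A statistics layer turns per-structure volumes
    into percentage-volume-change records and implements outlier exclusion,
    left/right averaging, test-retest reproducibility distances,
    between-method agreement matrices, group ANOVA with Tukey HSD post-hoc
    tests, and effect-size / sample-size estimation.  A synthetic-data module
    generates digitized shapes, analytic deformation fields with known volume
    change, and simulated multi-group cohorts so the whole pipeline can be
    exercised end to end without access-controlled imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
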
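Package: coneBeamSim
Title: Flexible Cone-Beam X-Ray Simulation and FDK Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Geometric simulation of X-ray projection imaging and
    filtered-backprojection reconstruction for fully configurable cone-beam
    systems. Provides ray-driven and distance-driven forward projection,
    voxel-driven and distance-driven backprojection, detector misalignment
    modelling (shifts, skew, roll, tilt), FDK-style weighted filtered
    backprojection, scan configurations (circular, helical, arbitrary
    source/detector poses, linear and arc tomosynthesis, wide field of view),
    memory-bounded chunk/set partitioning, synthetic digital phantoms, and
    raw/TIFF volume containers with a per-view calibration-file dialect.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
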
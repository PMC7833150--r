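Package: shinemap
Title: Lattice Dose-Response-Function Mapping of External Gamma-Ray Dose
    from Airborne Plumes and Surface Contamination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fast estimation of ground-level external gamma-ray dose-rate
    maps (cloud shine from an overhead radioactive plume and ground shine
    from deposited contamination) on Cartesian grids.  Doses are obtained
    by convolving gridded activity-concentration fields with pre-computed
    lattice dose-response functions built from a point-kernel model with
    Berger buildup factors, with straight-line attenuation through
    obstacle voxels, terrain-elevation index offsets, an analytic
    Gaussian-plume source model with Briggs dispersion curves, a
    synthetic building-array scenario generator, and a deterministic
    manager/worker parallel execution layer.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ncdf4,
    yaml,
    jsonlite,
    parallel,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
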
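Package: mssm
Title: Multiscale Structural Surface Mapping of the Cerebral Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Surface-based multiscale structural mapping (MSSM) of the
    cerebral cortex: intracortical depth surfaces and subjacent white-matter
    surfaces are sampled from a T1-weighted volume to form gray/white
    contrast-ratio features alongside cortical thickness, smoothed on the
    mesh, reduced per vertex with single-component partial least squares
    against diagnosis, analysed vertex-wise with FDR-corrected group
    contrasts and effect sizes, and fed to a class-weighted ensemble
    classifier with ROC/PR evaluation and transfer to a second cohort.
    Includes a synthetic cortical-phantom generator (spherical ribbon
    geometry, piecewise tissue intensities, bias field, configurable
    disease-like effects on thickness and contrast) so the whole pipeline is
    testable without real MRI, plus readers and writers for meshes (OFF,
    ASCII PLY, FreeSurfer binary), NIfTI-1 volumes, cohort tables and
    per-vertex maps, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    e1071,
    kernlab,
    randomForest,
    nnet,
    class,
    glmnet,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
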
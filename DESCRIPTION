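Package: cbct4d
Title: Simulation and Motion-Compensated FDK Reconstruction of Rapid
    Thoracic Cone-Beam CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-contained simulation study of respiratory-resolved thoracic
    cone-beam CT. Generates a parametric 10-phase digital thorax phantom with
    analytically known respiratory deformation fields, simulates conventional
    (1320 projections / 240 s) and rapid (491 projections / 16.6 s) full-fan
    cone-beam acquisitions by ray-driven forward projection, reconstructs with
    3D FDK filtered backprojection, respiratory-correlated 4D FDK, and
    motion-compensated FDK (MCFDK) using deformation vector fields, and scores
    image quality with contrast-to-noise ratio, tissue interface width,
    root-mean-square error, and structural similarity, including cohort
    summaries and paired t-tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
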
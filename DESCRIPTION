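Package: ctma
Title: CT-Based Motion Analysis of Lower-Leg Deformity by Contralateral
    Mirroring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies rotational and translational deformity of a lower
    leg by mirroring the contralateral side, rigidly registering the
    proximal bone segments as a stationary reference and the distal
    segments as a moving object, and decomposing the residual rigid
    transform into three centre-of-mass translations and three Euler
    rotations.  Includes STL surface I/O, Hounsfield-threshold seeded
    bone segmentation, trimmed iterative-closest-point surface
    registration with a mean-distance fit gate, a parametric synthetic
    leg-pair phantom generator with injectable deformities, and cohort
    left/right symmetry statistics (t-based confidence intervals,
    Shapiro-Wilk and Lilliefors normality tests).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nortest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    RNifti,
    optparse,
    yaml,
    testthat (>= 3.0.0)
SystemRequirements: C++11
Config/testthat/edition: 3
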
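Package: limbkin
Title: Limb Kinematics Clustering for Post-Stroke Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising post-stroke gait from sagittal-plane
    joint-center trajectories. Computes the limb extension angle and effective
    limb length of the paretic leg from hip/knee/ankle keypoints (e.g.
    markerless-capture output), segments gait cycles from shank angular
    velocity, normalises strides onto a 201-point gait-cycle basis, clusters
    participants with a full-covariance Gaussian mixture model selected by BIC
    and ICL, and compares clinical and gait variables across clusters with
    Kruskal-Wallis tests (epsilon-squared effect sizes) and Steel-Dwass
    all-pairs post-hoc tests. Includes a synthetic-walk generator with planted
    cluster structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
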
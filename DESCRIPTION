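Package: fishface
Title: Facial Landmark Morphometrics for Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometric phenotyping of the developing zebrafish
    face from rostral-view 2D anatomical landmarks. Provides a named, sided
    26-landmark coordinate system with readers and writers for ImageJ point
    lists, wide/long CSV and TPS files; an automated catalog of 39 facial
    measurements (distances, angles, areas and composites) with per-feature
    one-way ANOVA, Tukey post hoc tests and Bonferroni correction; feature-space
    principal component analysis with Kaiser retention, varimax rotation and
    PC-score logistic classification; and a complete landmark shape-analysis
    engine (generalized Procrustes superimposition on principal axes, object
    symmetry decomposition, shape PCA, canonical variate analysis and two-group
    discriminant function analysis with permutation tests, and wireframe
    visualization of mean-shape differences). A synthetic-data generator
    produces landmark datasets with the statistical structure the analyses
    assume (bilateral symmetry, group mean-shape offsets, digitization noise,
    pose jitter) so every pipeline stage is testable without images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS,
    optparse
Config/testthat/edition: 3
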
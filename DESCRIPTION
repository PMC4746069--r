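Package: asymmorph
Title: Geometric Morphometrics of Bilateral Symmetry and Fluctuating
    Asymmetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Procrustes-based analysis of shape variation and fluctuating
    asymmetry (FA) in structures with object symmetry, as applied to
    bilaterally symmetric organisms such as spatangoid echinoids.
    Provides generalized Procrustes superimposition with unit-centroid-size
    scaling, reflection-relabelling decomposition of each specimen into
    symmetric and asymmetric shape components, mixed-model Procrustes ANOVA
    (individual / side / individual-by-side / measurement error), principal
    component analysis of symmetric and asymmetric components, the full
    meristic FA protocol for bilateral counts (Grubbs outlier screen,
    size-dependence and normality checks, one-sample t test for directional
    asymmetry, FA1 and FA4a indices, Levene comparisons across populations),
    count-size allometry ANCOVA, categorical trait tabulation, readers for
    MeshLab PickPoints, TPS and CSV landmark files, and a synthetic-data
    generator with known variance components for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    xml2,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
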
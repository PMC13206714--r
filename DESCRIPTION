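Package: teatrace
Title: Trilinear Resolution and Origin Authentication for HPLC-DAD Tea Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Second-order calibration of three-way HPLC-DAD chromatographic data
    for flavan-3-ols and caffeine in raw dark tea. Implements alternating
    trilinear decomposition (ATLD) of elution-zone sub-cubes with core
    consistency diagnostics for component-number selection, spectral matching of
    resolved components to reference standards, regression-based quantification
    with full figures of merit (recovery, RMSEP, LOD/LOQ), and
    geographical-origin pattern recognition on the resulting analyte table:
    PCA, ternary feature-component analysis, LDA, PLS-DA with VIP scores, and
    t-SNE embedding with random-forest classification tuned on an L9 orthogonal
    design. A synthetic-data generator emulates the instrument's trilinear data
    cubes with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    randomForest,
    cluster,
    mixOmics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
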
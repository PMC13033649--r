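Package: perioimpute
Title: Denoising-Autoencoder Imputation Workflow for Periodontal Clinical Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying missing-data imputation in periodontal charting
    data. Simulates a synthetic cohort of virtual patients with probing depth,
    clinical attachment loss, furcation involvement and bleeding on probing at
    eight tooth sites; induces missing-completely-at-random holes in the
    tooth-site block; imputes them with a single-hidden-layer denoising
    autoencoder trained by full-batch gradient descent, and with mean, k-nearest
    neighbour and chained-equations baselines; and evaluates imputation quality
    with per-feature, category-weighted and overall MAE/RMSE, quadratic weighted
    kappa for ordinal agreement, and distribution summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
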
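Package: ocutort
Title: Quantitative Tortuosity Analysis of Retinal and Conjunctival Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Semi-automatic quantification of ocular vessel tortuosity from
    fundus and bulbar-conjunctiva photographs. Centerlines are extracted
    between operator-selected seed points by a minimal-cost path over a
    multiscale Hessian vesselness field, and three turning-angle tortuosity
    indices are computed on each traced segment: the sum of angles metric
    (SOAM), the product of angle-distance (PAD) and the triangular index
    (I2e). Includes a synthetic vessel-image and two-group cohort simulator
    with known ground-truth tortuosity, the case-control statistical
    analysis (exact/asymptotic Mann-Whitney comparisons, linear regressions
    on age and systemic covariates, demographic summaries), a seed-jitter
    reproducibility harness, and CSV/TIFF/PNG pipeline tooling.
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
    igraph,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
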
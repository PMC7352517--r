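Package: matricell
Title: Image-Based Stromal Matrix Models and Cell Migration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how collagen fiber morphology shapes cancer
    cell behavior on image-based scaffold models of the extracellular matrix.
    Provides seeded synthetic-data generators (fibrous matrix phantoms for
    four ovarian stromal morphology classes, persistent-random-walk cell
    trajectories, elliptical cell masks, punctate focal-adhesion images),
    conversion of fibrous grayscale images into discretized fabrication
    blueprints and modulated raster scan plans with a colocalization fidelity
    score, structure-tensor orientation analysis with circular statistics for
    axial data (Watson's two-sample U2, mean direction, alignment index),
    persistent-random-walk motility fitting from trajectory tables (motility
    coefficient and persistence time from the Furth mean-squared-displacement
    model), and cell morphometry (circularity, cell-to-fiber alignment angle,
    focal-adhesion detection, corrected total cell fluorescence), plus an
    end-to-end pipeline with group-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
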
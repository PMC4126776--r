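Package: phytocal
Title: Phytoplankton Calibration and Diatom-Based Transfer Functions for
    Water Quality Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating phytoplankton taxa against water-quality
    gradients and building diatom-based weighted-averaging (WA) transfer
    functions for total phosphorus (TP). Covers environmental-variable
    transformation and PCA summarization, per-taxon response modelling
    (linear, Gaussian unimodal, weighted-averaging optima, 0-10 indicator
    values, GAM permutation tests), WA regression with tolerance
    downweighting and inverse deshrinking, leave-one-out jackknife
    validation, the modern analog technique, spatial-autocorrelation stress
    tests (neighbourhood-deletion curves and a variogram-based randomization
    null), redundancy analysis with variance partitioning and passive
    projection of fossil samples, and downcore reconstruction diagnostics
    (lambda-R/lambda-P, reconstruction-versus-PCA correlation). A synthetic
    data module generates training sets, spatially autocorrelated
    environmental fields and sediment cores with known truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    vegan,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
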
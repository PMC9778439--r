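Package: lentileye
Title: Seed Size and Testa-Pattern Phenotyping of Lentils from Uncalibrated Photographs
Version: 0.1.0
Authors@R:
    person("Marta", "Greco", , "marta.greco@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for characterizing lentil (Lens culinaris)
    genetic resources from uncalibrated photographs of seeds on a dark
    background. Seeds are segmented with a randomized circle detector backed by
    statistical and radiometric plausibility checks; pixel radii are converted
    to millimetres via a 1 mm graph-paper strip pictured in-frame (scale factor
    S = ADV/EDV); and each seed's testa pattern is classified into the five
    canonical germplasm classes (absent, dotted, spotted, marbled, complex)
    through a two-step procedure combining an 18-bin rotation-invariant uniform
    local binary pattern signature, 180-bin RGB colour histograms, a
    gradient-boosted tree ensemble, and morphological region analysis. Includes
    a synthetic-scene generator with exact ground truth so every stage is
    testable without a physical dataset, plus the evaluation statistics
    (overall/balanced accuracy, support-weighted F1, size-error reports) used
    to benchmark such pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
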
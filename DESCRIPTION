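Package: drawrsa
Title: Representational Similarity Analysis of Children's Drawing Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies developmental and individual differences in a
    drawing-completion task where children draw freely on partially drawn
    objects (four categories, three presentation conditions). Provides a
    synthetic cohort generator (stroke-based child and adult drawing agents,
    noisy crowd raters, questionnaire sheets), the image preprocessing used
    for convolutional feature extraction (blue-to-black recoloring,
    presented-part removal, resizing and mean subtraction), a pluggable
    convolutional backbone exposing seven analysis layers, Pearson-distance
    representational dissimilarity matrices (RDMs) over stimuli and per
    child, crowd-rating aggregation with known-answer quality control,
    autism-spectrum-quotient scoring, and the statistical stages:
    mixed-model likelihood-ratio tests, permutation comparison of group RDMs
    against adults, and correlation of the per-child RDM score with the
    completion score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
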
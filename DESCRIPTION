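Package: catrep
Title: Identifying Within- Versus Between-Category Representations in
    Category Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates rule-based and information-integration
    category-learning sessions under classification (A/B) and concept
    (Yes/No) training, fits a within-category Gaussian density observer
    model and a between-category decision-bound observer model to each
    participant, and classifies each participant's learned representation
    by cross-validated generalization error on a novel transfer test.
    Includes bivariate-normal category structures with moment-matched
    stimulus sampling, synthetic observers for model- and
    parameter-recovery studies, and group-level summaries (blockwise
    accuracy, generalization RMSD tables, pooled two-proportion z tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
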
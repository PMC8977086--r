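Package: pretermrisk
Title: Fuzzy Analytic Hierarchy Process Risk Assessment of Preterm Birth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing the risk of preterm birth from expert
    linguistic judgments with the fuzzy analytic hierarchy process (FAHP).
    Implements triangular fuzzy number arithmetic and Ruspini linguistic
    scales, extent-analysis weight derivation from fuzzy pairwise comparison
    matrices, Saaty consistency checking on modal values, geometric-mean
    aggregation of multi-expert judgments, a weighted model-based diagnosis
    (MBD) score with linguistic classification, synthetic expert-panel and
    case-population generators with known ground truth, and a paired t-test
    protocol for validating model scores against aggregated expert diagnoses.
    All user-facing functions take and return tibbles so pipelines compose
    with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
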
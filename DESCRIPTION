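Package: spanscore
Title: Fragmentation-Penalized Evaluation of Span Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tokenizer-agnostic evaluation of span-extraction (clinical
    concept recognition) systems on character-offset annotations. Implements
    a Hoelder-mean "weighted soft matching" score that penalizes fragmented
    extractions of long target spans, with length-weighted aggregation into
    precision, recall and F1, alongside companion marker-, character- and
    token-level scores. Includes conversions between span annotations,
    binary character labels, inline '@@'/'##' marker text and token
    segmentations (with edit-distance alignment of generated text back to
    its source), length-stratified reporting, a generation-fidelity audit,
    cross-fold aggregation, and a seedable synthetic corpus and perturbation
    generator so every component is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
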
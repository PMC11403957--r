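Package: ccmqrapid
Title: Rapid Determination of TCM Body Constitution from CCMQ Item Subsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring, classification and item-reduction machinery for the
    60-item Constitution in Chinese Medicine Questionnaire (CCMQ). Implements
    converted-score computation with reverse scoring, the nine-type body
    constitution classification criteria, divisive principal-component
    variable clustering with representative-item selection, exhaustive
    item-subset search with cross-validated model selection and
    elbow/threshold choice of subset size, a synthetic Likert response
    generator with planted core items for validation, and an end-to-end
    analysis pipeline comparing supervised and unsupervised item selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    ranger,
    nnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    e1071,
    caret,
    mclust
Config/testthat/edition: 3
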
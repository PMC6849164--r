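Package: radincidence
Title: Rule-Based Detection of Positive Condition Incidence in Radiology Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Dictionary- and rule-based identification of free-text radiology
    reports with positive incidence of a clinical condition (for example
    hydronephrosis or brain metastasis). A condition mention is presumed
    positive unless a sentence-scoped negative-instance indicator (negation,
    evaluation, clinical history, resolution) applies; an optional
    last-occurrence step lets the final mention in a report decide the
    document label. Includes multiword gazetteer matching with UK/US spelling
    normalization, a declarative rule engine with ordered/unordered groups and
    token-gap limits, faceted indexing and search with highlighted snippets, a
    synthetic labeled-corpus generator for end-to-end testing, and a
    stratified review-sampling and precision/recall evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
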
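Package: nestedner
Title: Nested Biomedical Named Entity Recognition with Layered BIO Tagging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nested named entity recognition in biomedical text.
    Reads and writes brat standoff annotation, segments abstracts into
    sentences with offset remapping, encodes nested entity spans as up to six
    parallel layers of BIO tags, trains a multi-head token-classification
    model (a compact contextual encoder with six parallel per-token softmax
    heads over a 17-label space), builds per-type term dictionaries from
    MRCONSO.RRF-format concept files and merges dictionary matches with model
    predictions, and scores predictions with span-level exact-match
    precision, recall, micro F1 and macro F1. Includes a seeded synthetic
    corpus generator emulating the statistical structure of nested biomedical
    annotation so the full pipeline is testable without licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
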
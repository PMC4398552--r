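Package: sortscan
Title: Sort-Seq Scanning Mutagenesis Analysis of Yeast 3' End Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and analysis of massively parallel reporter
    assays that measure how yeast 3' end (terminator) sequences shape gene
    expression. Generates scanning- and saturation-mutagenesis libraries,
    simulates 16-bin FACS sort-seq read counts from gamma-distributed
    single-cell expression, infers per-variant mean expression by
    interval-censored maximum likelihood, localizes the TA-rich
    polyadenylation efficiency element from mutation-effect profiles, trains
    an L1-penalized logistic sequence model of the element with grouped
    cross-validation, and scores native 3' end sequences with it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
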
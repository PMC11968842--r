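Package: quiescreen
Title: Quiescence-Modulation Screening for Brain-Wide Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects behavioral quiescence bouts in multi-channel behavior
    recordings of freely moving C. elegans, computes a quiescence-modulation
    index (QMI) for identified neuron classes from brain-wide calcium traces,
    and screens classes for significant modulation against a two-state Markov
    surrogate null with empirical p-values and Benjamini-Hochberg false
    discovery rate control. Includes event-triggered averaging, plate-assay
    quantification helpers (feeding-rate conversion, quiescence categorization,
    bootstrap fraction intervals, chi-square comparisons), a synthetic-data
    generator that emulates multi-animal imaging sessions with Markovian bout
    structure and injected neural modulation, and delimited-text input/output
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
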
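Package: rtindex
Title: Rigor and Transparency Scoring of Biomedical Methods Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rigor-criterion statements (ethics approval, randomization,
    blinding, power analysis, sex reporting, cell-line authentication) and key
    biological resource mentions (antibodies, organisms, cell lines, plasmids,
    oligonucleotides, software tools) in the methods sections of biomedical
    articles, scores each paper on a 0-10 composite rigor-and-transparency
    scale, aggregates scores into a journal-year Rigor and Transparency Index
    (RTI), and compares the RTI against citation-based journal metrics by rank
    correlation. Includes a JATS XML reader, an RRID parser, a deterministic
    pattern engine with an optional trainable sequence tagger, and a synthetic
    methods-section corpus generator with ground truth for end-to-end
    evaluation.
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
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
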
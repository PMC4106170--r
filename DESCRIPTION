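Package: acacs
Title: Averaged Chemical Shift Composition Features for Protein Classification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds averaged chemical shift (ACS) reference tables from
    per-residue NMR backbone chemical shifts stratified by amino-acid type
    and three-state secondary structure, and encodes (sequence, secondary
    structure) pairs into fixed-length acACS feature vectors by replacing
    each residue with its ACS value and summarizing the series with lagged
    mean squared differences. Includes amino-acid and dipeptide composition
    features, an SVM jackknife (leave-one-out) evaluation harness with a
    with/without-acACS ablation protocol, parsers and writers for a minimal
    NMR-STAR-style chemical-shift format and paired sequence/secondary-
    structure text, and seeded synthetic-data generators for shift corpora
    and labeled sequence datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
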
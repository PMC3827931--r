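Package: rpiscore
Title: Sequence-Based Scoring of RNA-Protein Interaction Propensity
Version: 0.1.0
Authors@R:
    person("rpiscore", "maintainers", email = "rpiscore@example.org",
           role = c("aut", "cre"))
Description: Scores the interaction propensity of an RNA-protein sequence
    pair. Both sequences are encoded into fixed-length numeric channels
    (RNA secondary-structure pairedness, hydrogen-bonding and Van der
    Waals base propensities; protein Chou-Fasman structure, Grantham,
    Zimmerman, Kyte-Doolittle and Bull-Breese propensities), each channel
    is compressed to its leading cosine-series terms, channel pairs are
    scored with a Fisher-discriminant-trained bilinear form, calibrated
    to the open interval (0,100), and fused into a single interaction
    score. Includes training-set construction from PDB-format complexes
    (least-atom-distance labeling, length filters, redundancy removal),
    evaluation machinery (discriminative power, Matthews correlation,
    stratified cross-validation), deterministic synthetic-data
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
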
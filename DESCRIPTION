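Package: solscm
Title: Scoring Card Method for Protein Solubility Prediction from Dipeptide Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the solubility of proteins overexpressed in Escherichia
    coli from sequence alone using a scoring card of dipeptide propensities.
    A 400-entry solubility scoring matrix is estimated by statistical
    discrimination between soluble and insoluble training sequences,
    optionally refined by an intelligent genetic algorithm with
    orthogonal-array crossover maximizing a weighted sum of cross-validated
    AUC and conservation of the initial amino-acid propensities. Sequences
    are classified by comparing their composition-weighted score against a
    learned threshold, with an optional uncertainty region in which the
    classifier abstains. Includes propensity analysis of dipeptides, amino
    acids and physicochemical property scales, and a synthetic sequence
    generator with planted dipeptide biases for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
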
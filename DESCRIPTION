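Package: netsynergy
Title: Network-Based Prediction and Statistical Evaluation of Synergistic
    Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate drug pairs for a query disease by integrating
    three layers of evidence on a human molecular interaction network: the
    topological localization relationship between the disease module and the
    two drug modules (Complementary Exposure), degree-matched permutation
    z-scores of closest-distance network proximity, and transcriptional
    correlation between disease and drug expression signatures. Module gene
    sets can be amplified by random-walk network propagation with prior
    knowledge (PRINCE-style), using network-based disease similarity and
    chemical-fingerprint drug similarity as priors. Also provides the
    downstream statistics used to validate predicted combinations
    experimentally (Bliss independent-action and Loewe concentration-addition
    scores from dose-response plates), pathway-level mode-of-action analytics
    (over-representation, pathway coverage, largest-connected-component
    significance, differential-expression filtering), and a synthetic-data
    generator that plants known-synergy structure so the whole pipeline can
    be exercised and benchmarked offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
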
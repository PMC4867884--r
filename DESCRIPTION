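Package: ksegment
Title: k-Segment Constrained Inference for Hidden Markov Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Exact inference in discrete-state hidden Markov models under
    constraints on the number of segments in the hidden path.  The hidden
    chain is augmented with a deterministic counting Markov chain, which
    turns constrained MAP decoding, exact posterior probabilities over
    segment counts, and constrained posterior path sampling into ordinary
    dynamic-programming recursions on an extended state space, all linear
    in sequence length.  Supports generalized counting of selected
    transitions, excursion counting between null and abnormal state sets,
    constrained EM for prospective model fitting, and conjugate Gibbs
    sampling under segment-count constraints.  Applications include DNA
    copy-number segmentation and topic-segment retrieval in text.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
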
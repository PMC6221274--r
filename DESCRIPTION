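Package: dementialm
Title: Neural and N-Gram Language-Model Classification of Dementia Speech
    Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discriminates speakers with mild cognitive impairment or
    Alzheimer-type dementia from healthy controls using only the text of
    picture-description speech transcripts. Builds higher-order n-gram
    (4-gram/5-gram) document vocabulary spaces, reduces them to a continuous
    feature space by singular value decomposition, and trains multi-layer
    feed-forward neural-network language-model classifiers by minibatch
    stochastic gradient descent with L1/L2 regularization. Includes a
    class-conditional n-gram language-model baseline, evaluation by percent
    error, base-2 perplexity, and leave-pair-out cross-validated AUC with
    Hanley-McNeil variance, confidence intervals and p-values, and a seeded
    Markov-chain generator of two-group synthetic transcript corpora for
    method validation in the sparse clinical-data regime.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
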
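Package: streamFS
Title: Online Feature Selection for Sparse Streaming Features
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Online feature selection when features arrive as a stream and
    contain missing entries. Arriving feature columns are buffered into
    fixed-width sparse blocks, completed with a regularized latent-factor
    model trained by stochastic gradient descent on the observed cells only,
    and candidate subsets are chosen by an elitist genetic algorithm wrapped
    around a classifier, followed by conditional-independence relevance and
    redundancy pruning of the winning subset. Includes a synthetic stream
    generator with planted informative, redundant and noise features under a
    missing-completely-at-random mask, and the repeated cross-validation,
    Friedman and exact Wilcoxon signed-rank comparison protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    withr,
    caret,
    randomForest,
    rpart,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
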
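Package: mixodor
Title: Odor Profile and Origin Prediction for Complex Odorant Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts the sensory profile (top-5 odor descriptors and
    rate-all-that-apply scores) and the origin class of complex odorant
    mixtures, such as whiskies, from their detected volatile composition.
    Features are built by pairwise maximum-common-substructure comparison of
    a reference molecule pool; prediction uses the interpretable OWSum linear
    classifier (conditional-probability influence values with optional tf-idf
    weighting) and a small stack-and-pad convolutional network over
    per-molecule substructure applicability profiles, with educated-guess,
    inter-panelist, support-vector-machine and random-forest baselines and a
    leave-one-out evaluation harness. A synthetic mixture generator with
    planted class structure makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    e1071,
    igraph,
    graphics,
    jsonlite,
    methods,
    randomForest,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
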
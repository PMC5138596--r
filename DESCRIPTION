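Package: rgenescan
Title: Resistance-Gene Identification from Protein Sequences with
    Physicochemical Descriptors and Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies resistance (R) genes from protein sequences. Implements
    the 188-dimensional SVM-Prot descriptor (amino-acid composition plus
    composition/transition/distribution features over eight physicochemical
    property partitions), type-I pseudo amino acid composition (Pse-AAC),
    greedy sequence-identity clustering for redundancy removal, class-imbalance
    handling by random under-sampling or per-instance weighting, Random-Forest
    classification with pluggable baseline learners, and a full binary
    evaluation suite (sensitivity, specificity, accuracy, Matthews correlation,
    ROC area) under hold-out and stratified cross-validation. A synthetic
    sequence generator with tunable class signal makes every stage testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ranger,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
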
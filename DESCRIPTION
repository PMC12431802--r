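Package: sigscoreann
Title: Diagnostic Gene Signatures via Random Forests, Binary Gene Scores,
    and a Shallow Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a two-group transcriptomic diagnostic-signature
    workflow for case/control microarray studies: per-gene differential
    expression with pooled, Welch, or empirical-Bayes moderated t-statistics
    and Benjamini-Hochberg adjustment; random-forest ranking of
    differentially expressed genes with out-of-bag error curves and top-k
    signature extraction; a median-dichotomized binary gene-score statistic
    that encodes each sample as 0/1 per signature gene according to the
    gene's fold-change direction; and a single-hidden-layer feed-forward
    neural network trained by backpropagation on the score matrix, with ROC
    curve and AUC evaluation on training and independent test cohorts. A
    seeded synthetic-data generator emulating a 15-versus-15 microarray
    design with planted differential genes makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    randomForest,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
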
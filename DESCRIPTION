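Package: semindex
Title: Multi-Label Semantic Indexing of Biomedical Citations from Titles and Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Suggests controlled-vocabulary descriptors (MeSH-style main
    headings) for a document given only its title and abstract. Implements
    a k-nearest-neighbour label ranker -- TF.IDF/cosine retrieval over an
    annotated collection, six per-candidate-label features, pluggable
    classifiers (naive Bayes, decision tree, random forest, multilayer
    perceptron) for relevance scoring, and three label-count selection
    strategies including a score-ratio cut-off rule -- together with a
    standalone explicit-semantic-analysis classifier built from
    term-concept association scores (TF.ICF or Jaccard), example-based
    multi-label evaluation metrics, and a synthetic corpus generator with
    planted label-term associations for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    e1071,
    rpart,
    ranger,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
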
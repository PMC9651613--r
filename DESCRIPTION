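Package: nbfbind
Title: Neural Bellman-Ford Networks for DNA-Protein Binding Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA-protein binding as link prediction on a homogeneous
    interaction graph. Implements an exact generalized Bellman-Ford path
    engine over pluggable semirings (graph distance, Katz index, widest path,
    most reliable path, personalized PageRank), its neural parametrization
    with indicator/message/aggregate functions (DistMult, TransE, RotatE
    messages; sum, mean, max aggregation), SortPooling and trainable
    log-mean-exp (AlphaMEX) global pooling, a three-module architecture with
    a fully connected head trained by negative log-likelihood with entity
    corruption negative sampling, stratified k-fold cross-validation,
    confusion-matrix metrics with MCC and AUROC, and a latent-factor
    synthetic generator of bipartite DNA-protein benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml,
    Biostrings
Config/testthat/edition: 3
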
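Package: heteroDTI
Title: Drug-Target Interaction Prediction via Heterogeneous Network Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTIs) from a heterogeneous
    network decomposed into a bipartite interaction network plus drug-drug and
    target-target similarity networks. Learns bipartite embeddings with
    Co-HITS implicit-transition matrices, truncated random walks with restart
    and skip-gram training with negative sampling; screens similarity matrices
    by entropy and redundancy and fuses the survivors by similarity network
    fusion; builds path-augmented embeddings of every drug-target pair; and
    scores unknown pairs with a class-weighted random forest under
    entity-wise (cold-start) cross-validation. Includes a synthetic data
    generator with planted block structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
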
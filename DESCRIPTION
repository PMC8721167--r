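Package: ddinet
Title: Drug-Drug Interaction Type Prediction from Fused Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the type of interaction between drug pairs by fusing
    heterogeneous drug similarity networks. Binary descriptor profiles
    (chemical substructures, targets, pathways, enzymes) are turned into
    Jaccard similarity networks and ATC codes into a hierarchy-prefix
    similarity network; each network is diffused by random walk with restart
    and re-expressed as positive pointwise mutual information; the five
    topological networks are fused into one unified drug embedding by a
    multimodal deep autoencoder; and a softmax deep neural network classifies
    drug pairs into interaction types. Includes a synthetic-data generator
    with planted group structure, cold-start cross-validation scenes for
    unseen drugs, micro/macro multiclass evaluation, and ablation variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
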
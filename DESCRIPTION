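Package: ammgc
Title: Attentive Multimodal Graph Convolutional Link Prediction for
    miRNA-Drug Resistance Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts miRNA-drug resistance associations from a bipartite
    association graph and multimodal node features. Four two-layer graph
    convolutional sub-networks encode distinct drug-feature/miRNA-feature
    combinations (substructure fingerprints, label-encoded SMILES,
    expression profiles and GO-based similarities); a reduced-parameter
    attention network rescales each modal embedding dimension-wise and
    concatenates them, and associations are scored by the inner product of
    the fused embeddings. Includes negative-sampling and class-weighted
    cross-entropy training, a repeated cross-validation harness with
    ranking metrics (AUPR, AUC, F1, accuracy, recall), a synthetic
    bipartite-data generator with planted low-rank structure, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
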
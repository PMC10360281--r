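Package: fragssl
Title: Fragment-Based Dual-Channel Self-Supervised Pretraining for
    Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Self-supervised pretraining of graph neural network encoders
    on unlabeled molecule libraries, using BRICS fragments to build the
    supervisory signal through two channels: a contrastive channel that
    aligns a fragment-attentive molecular embedding with the plain
    atom-level embedding via an InfoNCE objective, and a generative
    channel that reconstructs masked atom features from intra-fragment
    context under a scaled cosine error.  Includes SMILES parsing and
    featurization, BRICS atom partitioning, a GIN message-passing encoder
    with a built-in reverse-mode differentiation tape, Murcko scaffold
    splitting, fine-tuning with a task head, linear probing, and ROC-AUC /
    RMSE evaluation, plus a deterministic toy-library generator so the
    whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
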
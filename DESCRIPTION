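Package: moorle
Title: Entropy-Regularized Multi-Objective Loss for Imbalanced Drug
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for drug response prediction on imbalanced pair-input
    datasets. Implements the MOORLE loss (Multi-Objective Optimization
    Regularized by Loss Entropy): the mean of per-drug mean squared errors
    plus an entropy penalty a*(ln|D| - H(P)) on the softmax-normalized
    per-drug loss distribution P, which pushes a regressor toward balanced
    performance across drugs. Includes group-aware minibatch samplers
    (sequential shuffled and mixed weighted sampling), random-pair and
    drug-blind cross-validation split plans with leakage validation, a
    reference fully connected neural network trained by minibatch Adam
    with either loss, bulk/per-drug/drug-averaged/MOA-averaged evaluation
    metrics, and a synthetic data generator emulating the long-tailed
    per-drug experiment-count profiles of public cell-line screens.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
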
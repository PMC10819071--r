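Package: crossmol
Title: Knowledge-Augmented Sequence-Graph Cross-Attention Models for
    Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("crossmol", "developers", email = "crossmol@example.org",
           role = c("aut", "cre"))
Description: Dual-branch neural architecture for predicting molecular
    properties from SMILES strings.  A molecular graph branch augments
    each molecule with virtual knowledge nodes (discretised periodic-table
    element properties and matched functional groups) and encodes the
    augmented graph with a dual-channel attention message-passing network
    (GAT-style attention coefficients, GRU node updates, Set2Set readout).
    A sequence branch segments the SMILES string over a mined
    frequent-consecutive-subsequence vocabulary and encodes it with a
    transformer.  The two embeddings are fused by cross-attention and
    decoded into classification or regression predictions.  Includes a
    reverse-mode automatic-differentiation engine, an end-to-end training
    harness with scaffold splits and early stopping, ablation modes, a
    synthetic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
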
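Package: foldstack
Title: Ensemble Prediction of RNA Secondary Structure from Base-Learner Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combines the secondary-structure predictions of several RNA
    folding algorithms ("base learners") into a single consensus structure.
    Two ensemble strategies are provided: a convolutional block attention
    network that re-weights learner channels and spatial regions of the
    stacked contact maps, and a lightweight learnable softmax weighting of
    the learner matrices. Both are trained with positively re-weighted
    binary cross-entropy and decoded under the hard constraints of RNA base
    pairing (canonical plus wobble pairs, minimum loop distance, at most
    one partner per base) via exact maximum-weight matching or an iterative
    relaxation. Includes readers and writers for FASTA, dot-bracket, CT and
    BPSEQ formats, a synthetic structure generator and base-learner
    simulator for controlled experiments, base-pair evaluation metrics
    (precision, recall, F1, interaction network fidelity), Jaccard
    concordance analysis, ROC curves, exhaustive ensemble-combination
    search, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    seqinr,
    pROC,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
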
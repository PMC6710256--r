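Package: sspredict
Title: Protein Secondary Structure Prediction with Profile Encodings and
    Cascaded Recurrent-Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable, desk-scale implementation of a profile-based
    protein secondary structure predictor. Reads FASTA sequences and
    query-anchored multiple sequence alignments (aligned-FASTA and A3M),
    builds per-residue input encodings (one-hot, plain and
    entropy-weighted alignment profiles, clipping, profile combination,
    three-state augmentation), and labels each residue with 3- or 8-state
    DSSP secondary structure using either window-based feed-forward
    networks or a two-stage cascaded bidirectional recurrent and
    convolutional network trained by stochastic gradient descent with
    momentum and an adaptive learning rate. Includes softmax-averaging
    ensembles with a 3-to-8-state cascade, Q3/Q8 and segment-overlap
    (SOV'99, refined SOV) evaluation, a synthetic dataset generator with
    secondary-structure segment statistics and simulated homolog
    alignments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
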
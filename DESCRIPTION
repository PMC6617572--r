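Package: pinnCPI
Title: Pairwise-Input Neural Networks for Compound-Protein Interaction
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Proteochemometric modelling of compound-protein interactions
    with single- and multi-channel pairwise-input neural networks (PINNs).
    Provides character-level one-hot encoding of SMILES and amino-acid
    sequences, Morgan-substructure and N-gram "sentence" featurization with
    skip-gram word embeddings and sum/mean/TF-IDF aggregation, ECFP-style
    circular fingerprints, a native network engine (dense, dilated
    convolution and LSTM/BLSTM channels trained with Adam on class-weighted
    cross-entropy), MCC/ROC/PRC evaluation with z-score model ranking, a
    pretrain-checkpoint/finetune transfer protocol, and a calibrated
    synthetic CPI data generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
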
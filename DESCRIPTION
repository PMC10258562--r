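Package: cpae
Title: Compositional Perturbation Autoencoders for Single-Cell Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models single-cell gene expression under drug and genetic
    perturbations as an adversarially disentangled basal state plus additive
    perturbation and covariate embeddings in latent space. Provides
    containers for annotated expression data built on SummarizedExperiment,
    a synthetic data generator with known ground truth, training of the
    compositional perturbation autoencoder with its two-phase adversarial
    loop, counterfactual prediction of unseen perturbation/dose/covariate
    combinations with distance-based uncertainty scores, evaluation against
    random and linear baselines, and rule-based classification of pairwise
    genetic-interaction modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    igraph,
    cluster
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    rhdf5,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, GeneExpression, Software
RoxygenNote: 7.3.3
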
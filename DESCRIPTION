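Package: sadasnet
Title: Selective and Adaptive Deep Architecture Search with Particle Swarm
    Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Particle-swarm-driven neural architecture search for
    convolutional image classifiers, aimed at multi-class dermoscopy
    (skin lesion) classification. Candidate macro-architectures built from
    serial and multi-branch (inception-style) convolution blocks, optional
    pooling and fully connected layers are encoded as fixed-length vectors
    of reals in [0, 1], decoded through a bounded denormalization rule,
    repaired for shape feasibility, screened against hardware budgets, and
    trained under a fixed stochastic-gradient protocol. Includes a compiled
    CNN training backend, a class-conditional synthetic image generator with
    controllable separability, a HAM10000-style folder/CSV reader, a
    class-balancing planner with pluggable oversampling, full multiclass
    evaluation reports (confusion matrix, precision, recall, F1,
    specificity, one-vs-rest ROC-AUC, Cohen's kappa), and command-line
    entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    png,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
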
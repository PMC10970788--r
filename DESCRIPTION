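Package: greenodor
Title: Fingerprint-Based Classification and Chemical-Space Analysis of Green Odorant Molecules
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate binary classifiers of "green odor"
    (the grassy scent of fresh leaves, classically attributed to C6 alcohols
    and aldehydes) from molecular structure. The package cleans and balances
    labelled SMILES tables, converts molecules to 2048-bit radius-2 circular
    (Morgan) fingerprints and a physicochemical descriptor battery, trains a
    multilayer perceptron, a support vector machine and a random forest under
    a uniform prediction contract, scores them with repeated stratified
    cross-validation (precision, accuracy, recall, F1, MCC, AUC, average
    precision, averaged confusion matrices), embeds the positive class in two
    dimensions, clusters it with a distance-cutoff rule, builds a
    Dice-weighted chemical space network with representative-molecule
    selection, and contrasts the two classes by factor-analysis descriptor
    screening followed by a normality-gated two-sample testing tree.
    A synthetic SMILES generator emulating the two odor classes makes every
    stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    e1071,
    ranger,
    igraph,
    car,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
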
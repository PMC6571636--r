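Package: cpann
Title: Counter-Propagation Neural Networks for Multiclass QSAR Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Multiclass classification of molecular descriptor tables with
    counter-propagation artificial neural networks (CP-ANN). Provides Kohonen
    self-organizing maps for dataset splitting and descriptor reduction,
    descriptor preprocessing (autoscaling, variance and correlation filters),
    genetic-algorithm descriptor selection with CP-ANN fitness, multiclass
    evaluation via non error rate (NER), average precision (AvPr) and
    per-class Matthews correlation coefficients, and a Euclidean-distance
    applicability-domain assessment. Includes a synthetic descriptor-table
    generator emulating P-glycoprotein inhibitor/substrate/non-active
    datasets.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
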
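Package: fosplace
Title: Fos Induction and Hippocampal Place Coding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline relating immediate-early-gene (Fos)
    induction to hippocampal place coding in head-fixed virtual-reality
    experiments. Provides significance calling for calcium (dF/F) transients with
    an empirical false-positive-rate criterion, place-field detection against a
    block-permutation behavioural shuffle null, spatial information, Poisson
    naive-Bayes position decoding on a circular track, activity matching between
    cell groups, fold-induction image quantification, trial-wise ensemble
    correlation and affinity-propagation clustering, and activity-weighted
    cross-day place-field stability maps. A synthetic virtual-track data
    generator with known ground truth makes every stage testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    tiff,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
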
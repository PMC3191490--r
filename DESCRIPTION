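Package: stepnet
Title: Stepwise Network Inference for Gene Regulatory Networks from
    Perturbation Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs directed, signed gene regulatory networks from
    perturbation expression compendia under a steady-state linear
    ordinary-differential-equation model, using per-gene forward/backward
    stepwise regression with partial F-tests (stepwise network inference,
    SWNI). Includes a scale-free network simulator for ground-truth
    benchmarking, a deterministic per-gene parallel execution engine with
    speedup/efficiency reporting, microarray-style preprocessing
    (probe-to-gene mapping, quantile normalization, batch mean-centering),
    and downstream network analytics: degree statistics, hub detection,
    directed pathway enumeration, merging with protein-protein interaction
    data, localization summaries, and qPCR relative quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    igraph,
    jsonlite,
    limma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
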
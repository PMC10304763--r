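Package: cfMethTools
Title: Cell-Free DNA Methylation Deconvolution and Methylation Biomarker
    Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for plasma cell-free DNA (ccfDNA) methylation analysis:
    construction of cell-type-specific CpG signature matrices from reference
    methylation atlases, estimation of cell-type-of-origin proportions of bulk
    bisulfite profiles with four interchangeable regression models (NNLS, SVR,
    QP, RLM), simulation-based model benchmarking, mapping of WGBS methylation
    calls to array probe identifiers, tiled differential-methylation calling,
    severity-association screening of differentially methylated regions with a
    ccfDNA-level covariate, cross-platform normalization of targeted bisulfite
    panels (pseudo-count log transform, target quantile normalization,
    empirical-Bayes batch adjustment), and acute-coronary-syndrome type
    classification. Includes a synthetic-data module that emulates reference
    atlases, WGBS cohorts with planted differentially methylated regions and
    severity trends, and targeted panels with batch effects, so the whole
    pipeline is exercisable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    e1071,
    quadprog,
    pracma,
    nnet,
    randomForest,
    glmnet,
    sva,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
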
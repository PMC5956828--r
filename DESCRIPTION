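Package: embedclass
Title: Embedding-Space Classification and Anomaly Detection for Histology Tiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transparent, statistically driven classification of
    whole-slide histology images from deep feature embeddings of image tiles.
    Tile feature vectors are projected onto a two-dimensional reference map
    (t-SNE or PCA) built from labelled training tiles; new tiles are
    discretized into trained classes or flagged as outliers by a
    nearest-neighbour purity rule, and slide-level verdicts (diagnosis,
    differential diagnosis, undefined) are rendered by iterative chi-square
    testing of the tile distribution. Includes a lesional-probability gating
    step, class-activation-map rendering by tile reassembly, a softmax
    probability baseline with composite (combined and hybrid) classifiers,
    multiclass ROC evaluation with error typing, and a synthetic fixture
    generator that emulates class-clustered CNN feature spaces for testing
    open-set behaviour without a trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    Rtsne,
    jsonlite,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'assign.R'
    'decision.R'
    'evaluation.R'
    'fixtures.R'
    'io.R'
    'pipeline.R'
    'provider.R'
    'refmap.R'
    'tiling.R'
    'utils.R'
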
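Package: spinemorph
Title: Decision Framework for Dendritic Spine Morphometry, Embedding
    Selection and Probabilistic Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling dendritic spine morphology as a continuum
    rather than a set of discrete classes. Extracts shape, contour and
    intensity features from two-dimensional spine crops, compares
    dimensionality-reduction embeddings (PCA, ISOMAP, t-SNE, UMAP and a
    correlation-refined UMAP) with local, global and biologically informed
    structure-preservation metrics including a Biological Transition Score,
    selects and runs probabilistic clustering (Ward, fuzzy c-means,
    Gaussian mixtures) with cluster-number diagnostics, and quantifies
    transitional and ambiguous morphologies. Ships a synthetic spine
    generator emulating the mushroom/stubby/thin continuum for end-to-end
    validation without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    e1071,
    FNN,
    igraph,
    jsonlite,
    mclust,
    pracma,
    Rtsne,
    stats,
    tiff,
    utils,
    uwot,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
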
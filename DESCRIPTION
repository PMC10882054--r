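Package: colwire
Title: Heterogeneity of Columnar Synaptic Wiring in the Fly Optic Lobe
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies presynaptic-input heterogeneity across retinotopic
    columns of the Drosophila optic lobe from automatically detected synapse
    tables. Implements synapse-table quality filtering (cleft-score cutoff,
    redundancy removal, per-cell partner thresholds), connectivity-matrix
    construction (absolute, relative, binary), heterogeneity statistics
    (pairwise cosine similarity with Kruskal-Wallis/Dunn group tests,
    per-input variation, rank order), motif discovery (Pearson input
    correlations, k-means subtypes, PCA, Hamming-distance agglomerative
    clustering with silhouette model selection), spatial mapping
    (column coordinates, dorsoventral split, presence maps, join-count
    randomness test), an expansion-microscopy synapse-apposition counter
    (puncta detection, mask binarization, distance-thresholded counts per
    column ROI), and calcium-trace normalization and clustering
    (mean-augmented dF/F, z-scoring, correlation-distance k-means).
    A synthetic-data module generates connectomes, two-channel volumes and
    trace sets with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    jsonlite,
    yaml,
    tiff,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
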
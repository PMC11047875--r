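Package: eegcluster
Title: Unsupervised Adaptive Clustering of Epileptic EEG Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised analysis pipeline for fixed-length epileptic EEG
    segments: joint denoising by complete ensemble empirical mode
    decomposition with adaptive noise (CEEMDAN) plus correlation-based mode
    screening and Daubechies wavelet thresholding; extraction of a
    twelve-feature multivariate description (time, frequency, time-frequency
    and nonlinear measures); exact t-SNE embedding; DBSCAN clustering with
    radius and density parameters selected adaptively by the sparrow search
    algorithm using the silhouette coefficient as fitness; and clustering
    quality evaluation with silhouette, Calinski-Harabasz and Davies-Bouldin
    indices combined into a coefficient-of-variation composite score. Includes
    a seeded generator of EEG-like multi-class synthetic segments so the whole
    pipeline is testable without recordings, and CSV/EDF readers and writers
    for every intermediate artifact.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    igraph,
    Rtsne,
    optparse,
    knitr
Config/testthat/edition: 3
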
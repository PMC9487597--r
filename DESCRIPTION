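Package: scRescale
Title: Composition-Aware Re-Scaling Integration of Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates single-cell RNA-seq datasets across platforms
    (plate-based full-length and droplet-based), tissues and batches by
    correcting the cell-type-composition effect on per-gene unit-variance
    scaling. Clusters each dataset, aligns clusters across datasets in a
    joint principal-component space using a quantile spread criterion with
    a subsampling retry, derives per-gene scaling factors from
    composition-matched subsamples, re-scales both datasets and selects the
    clustering resolutions that minimise a neighbourhood mixing metric,
    falling back to plain concatenation when re-scaling does not help.
    Includes k-nearest-neighbour label transfer with match scores,
    integration quality metrics (mixing, local structure preservation,
    silhouette width, adjusted Rand index), sequential multi-dataset
    integration ordered by shared highly variable genes, and a synthetic
    multi-platform data generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    RANN,
    irlba,
    cluster,
    matrixStats,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
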
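Package: cellfetch
Title: Format-Agnostic Data Access for Single-Cell Datasets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A unified data-access layer for single-cell datasets stored
    on disk in the AnnData (h5ad), loom, 10x Genomics Matrix Market and
    10x Genomics feature-barcode HDF5 formats. One grammar of variable
    requests (metadata columns, feature expression with optional modality
    key and layer, reduction dimensions such as "UMAP_1") is resolved
    against a per-dataset catalog, and results are returned as a single
    cell-by-variable data.frame regardless of the storage format. Backed
    access reads only the slices a request needs, so single-feature
    fetches from compressed sparse matrices never materialize a full
    expression matrix. Includes a synthetic multimodal fixture generator
    (RNA plus ADT, UMAP/t-SNE/PCA embeddings) that writes ground-truth
    datasets to every supported format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, Matrix, rhdf5
Suggests: testthat (>= 3.0.0), arrow, jsonlite, withr
Config/testthat/edition: 3
biocViews: SingleCell, DataImport, Infrastructure, Software
RoxygenNote: 7.3.3
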
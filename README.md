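# cellfetch

Format-agnostic data access for single-cell datasets in R.

Single-cell analysis suites keep their data in incompatible containers, and
the practical fallback — converting whole objects between formats — is slow,
lossy and brittle. `cellfetch` takes the other road: it leaves datasets in
their native on-disk form and answers one kind of question uniformly across
formats — *give me these variables for these cells, as one table*. The same
request works against:

- **h5ad** files (the AnnData on-disk specification, v0.8+ element
  encodings, with dense, CSR or CSC matrices),
- **loom** files,
- **10x Genomics Matrix Market directories**
  (`matrix.mtx[.gz]` + `barcodes.tsv[.gz]` + `features.tsv[.gz]`),
- **10x Genomics feature-barcode HDF5** files (CellRanger v3 layout).

## The request grammar

All data is requested through character vectors of *vars*. Each var is
classified against the dataset's catalog by a fixed precedence:

1. `"<REDUCTION>_<d>"` — a 1-based dimension of a reduction
   (`"UMAP_1"`, `"pca_3"`; key matching is case-insensitive);
2. `"<modality>_<feature>"` — feature expression from a named modality
   (`"adt_CD117"` for a surface-protein count in CITE-seq data);
3. an exact metadata column name (`"cell_type"`);
4. a bare feature name, looked up in the default modality (`"CD34"`).

Only the first underscore is examined, and only prefixes naming a cataloged
modality or reduction count as keys, so feature symbols that merely contain
underscores (`"HLA_DRA"`) resolve whole. The result is always a single
`data.frame`: one row per cell (row names are the cell barcodes), one column
per request, in request order.

Expression matrices are read lazily: in backed mode, fetching one feature
from a compressed-sparse-column h5ad touches only that column's slice of
`data`/`indices` plus two `indptr` entries — never the full matrix. The
handle counts every matrix element it materializes (`ioCount()`), which
makes the access-cost contract testable.

## Worked example

No download needed — the package generates a known-truth multimodal dataset
(RNA + ADT, UMAP/t-SNE/PCA, 200 cells) and writes it to every format:

```r
library(cellfetch)
ld    <- makeFixture(fixtureSpec(seed = 1))
paths <- writeAllFormats(ld, tempfile("demo"))
ds    <- openDataset(paths[["h5ad_csc"]], mode = "backed")
ds
#> <H5ADSource> h5ad dataset, backed mode: .../fixture_csc.h5ad
#> DataCatalog: 200 cells
#>   modality rna (default): 60 features; layers: counts, data [default data]
#>   modality adt: 12 features; layers: counts, data [default data]
#>   reductions: pca (key PCA, 10 dims); tsne (key TSNE, 2 dims); umap (key UMAP, 2 dims)
#>   metadata columns: cell_type, batch, quality_score
#>   elements read: 0

head(fetchData(ds, c("cell_type", "CD34", "adt_CD117", "UMAP_1")), 4)
#>             cell_type     CD34 adt_CD117    UMAP_1
#> cell_000001      Mono 7.947002  7.180113 -3.513158
#> cell_000002      Mono 0.000000  6.959998 -2.407995
#> cell_000003         T 0.000000  6.418764 10.538355
#> cell_000004         B 6.250441  7.062122 -3.584455
```

One table, four kinds of value: a cell-type label, log-normalized RNA
expression of CD34, the ADT (antibody) signal for CD117, and the first UMAP
coordinate — each pulled from the right matrix by the grammar above. The
same call against `paths[["loom"]]` or any other output returns the same
numbers. The specific accessors are faster, unambiguous spellings of the
same contract:

```r
uniqueValues(ds, "cell_type")
#> [1] "Mono" "T"    "B"    "HSC"  "NK"
defaultReduction(ds)   # searches UMAP, then t-SNE, then PCA
#> [1] "umap"
fetchReduction(ds, dims = c(1, 2), cells = head(getAllCells(ds), 100))
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/cellfetch-cli`:

```sh
cellfetch-cli fetch demo/fixture_csc.h5ad --vars cell_type CD34 UMAP_1 \
    --out table.csv
cellfetch-cli unique demo/fixture.loom --var cell_type
```

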
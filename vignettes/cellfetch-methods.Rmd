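---
title: "cellfetch: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellfetch: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellfetch)
```

# The access model

`cellfetch` answers one question against any supported storage format:
*for these cells, give me these variables as one table*. A variable may be
a per-cell metadata column, the expression of one feature in one modality
and layer, or one dimension of a low-dimensional embedding. The answer is
always a plain `data.frame` with cell barcodes as row names and one column
per request, in request order — the shape every downstream plotting or
modeling function accepts. The package does no analysis: no object
assembly, clustering, filtering or normalization beyond what is already in
the file. That restraint is what keeps the surface identical across
formats.

Internally every dataset is reduced to the same two objects at open time:

* a `DataCatalog` — the inventory of modalities, features, layers,
  reductions (with their column-name keys and dimensionalities), metadata
  columns and cell IDs; and
* a `SingleCellSource` handle that knows how to read one metadata column,
  one feature vector, or one reduction column from its format.

Metadata tables and reduction coordinate matrices are always read eagerly:
they are a few kilobytes to a few megabytes and are needed to build the
catalog anyway. Expression matrices are the asymptotically large part and
are the only thing the backed/in-memory distinction applies to.

# The request grammar

Each requested string is classified by a fixed precedence:

1. **keyed reduction dimension** — the prefix before the *first*
   underscore names a reduction (by name or key, case-insensitively) and
   the remainder is all digits. `"UMAP_2"` is the second UMAP dimension.
   A digit remainder outside `1..nDims` is rejected with
   "dim out of range" rather than falling through: a user who wrote
   `"UMAP_3"` on a 2-D embedding almost certainly meant a reduction
   dimension, and silently reinterpreting it would mask the mistake.
2. **keyed feature** — the prefix names a modality and the remainder is,
   case-sensitively, one of its features (`"adt_CD117"`). If the remainder
   is not a feature the rule simply does not fire and later rules get
   their chance, so a metadata column that happens to start with a
   modality name (`"rna_batch"`) remains reachable.
3. **exact metadata column name**.
4. **bare feature in the default modality**.

A bare name found only in a *non-default* modality is rejected as
"ambiguous without modality key" whenever the dataset has more than one
modality. Key-less feature access is honored only where it cannot
mislead — single-modality datasets — because a silent cross-modality search
would make `"CD34"` mean different things in RNA and ADT space depending
on catalog contents.

Two consequences of the precedence are worth stating plainly. A metadata
column literally named like a feature (`"CD38"`) wins over the bare
feature; the keyed spelling (`"rna_CD38"`) reaches the feature. And only
the first underscore is ever considered as a key separator, so
underscore-containing feature symbols (`"HLA_DRA"`) survive whenever their
prefix is not a cataloged key.

Batch resolution deduplicates verbatim repeats (first occurrence wins,
keeping column order stable), drops unresolvable requests with a warning,
and errors only when *nothing* resolves. The specific accessors are
stricter on purpose: `fetchMetadata()` rejects anything that is not a
metadata column rather than inferring, because the point of a dedicated
accessor is to be unambiguous and to guarantee it never touches an
expression matrix.

Warnings are routed through a pluggable reporter
(`options(cellfetch.reporter = function(msg) ...)`), defaulting to R's
`warning()`, so pipelines can capture or redirect them.

# Catalog mapping per format

**h5ad.** The main matrix (`X`, `var`, `layers/`) is cataloged as the
modality `"rna"`. Plain AnnData has no standard slot for a second
modality, so additional modalities are read from top-level `mod/<name>`
groups — the MuData-style layout the fixture writer also emits. This is an
extension point of this package, not part of the AnnData specification;
files using it are not readable by plain Python `anndata` (single-modality
outputs are). Layer names come from `layers/` when the group exists and is
non-empty; otherwise the main matrix is exposed as the single layer
`"X"`. Entries of `obsm` named `X_<name>` (or bare `<name>`) become
reductions with key `toupper(name)`. Categorical obs columns
(codes/categories encoding) are decoded to labels, with the code −1
decoded to `NA`.

**loom.** The matrix and layers are genes × cells; `row_attrs/Gene` and
`col_attrs/CellID` name features and cells. loom has no dedicated
reduction slot, so this package adopts the convention that 2-D column
attributes are reductions (key = upper-cased attribute name) and 1-D
column attributes are metadata. Without a `layers/` group the main matrix
is exposed as the layer `"matrix"`.

**10x formats.** Both the Matrix Market directory and the feature-barcode
HDF5 carry exactly one modality (`"rna"`) with the single layer
`"counts"`, no reductions, and no metadata — barcodes are cell IDs, not
metadata. Feature names are the feature IDs (first column of
`features.tsv`, or `matrix/features/id`); duplicated names are
disambiguated as `name`, `name.1`, `name.2`, … in file order, mirroring
common R practice.

The default layer per modality is `"data"` if present, else `"counts"`,
else the format's main matrix. This mirrors the common convention that
`data` holds normalized expression and `counts` raw counts; it also means
a layer-less request returns the same values from an h5ad and a loom
rendering of the same dataset, while the 10x formats — which can only
carry counts — are reachable with an explicit `layer = "counts"`.

Matrix orientation is a per-format constant, never inferred: h5ad `X` is
cells × features on disk, loom and both 10x formats are features × cells.
Backends normalize so a feature vector is always per-cell in native cell
order.

# Backed access and the I/O counter

In backed mode, a feature fetch reads only what the storage layout
permits:

* **CSC h5ad** (features are the major dimension): two `indptr` entries
  plus the column's own slices of `data` and `indices` — `2·nnz(column) + 2`
  stored elements.
* **CSR h5ad and 10x HDF5** (cells are the major dimension): a chunked
  scan of `indices` is unavoidable; the documented cost is O(nnz of the
  whole matrix).
* **dense h5ad / loom**: one row or column, `nCells` elements.
* **Matrix Market** has no sliceable layout and is materialized at open in
  either mode.

Every handle counts the stored elements it materializes (`ioCount()`).
The counter exists to make the access-cost contract *testable*: the suite
asserts that a single-feature fetch from a 50,000-cell backed CSC file
stays within `2·nnz(column) + 4` elements and that `fetchMetadata()`
leaves the counter at zero. In-memory mode counts the one-off
materialization at open and nothing afterwards. Backed and in-memory
handles must return identical values; only the counter trajectories
differ.

# The fixture generator

`makeFixture()` draws a dataset whose every value is known
(`LogicalDataset`), and `writeAllFormats()` renders it to six outputs:
h5ad with dense, CSR and CSC matrices, loom, a Matrix Market directory,
and a 10x HDF5 file, each restricted to the format's capabilities. The
defaults — 200 cells, 60 RNA and 12 ADT features, `counts` plus
log-normalized `data` layers, UMAP/t-SNE embeddings with a 10-dimensional
PCA, a five-level cell-type label, a two-level batch label, one numeric
quality score, and 80% zeros in RNA counts — are a desk-scale stand-in for
a multimodal bone-marrow reference of a few hundred surface markers and a
few hundred mRNAs; full-scale generation is just a parameter choice.

Mechanically: counts are negative-binomial draws (RNA: mean 5, dispersion
size 2; ADT: mean 30, size 5) with entries zeroed by an independent
Bernoulli mask at the requested sparsity — ADT uses half the RNA sparsity
because antibody panels are far denser than transcriptome-wide RNA. The
`data` layer is `log1p` of depth-normalized counts (scale 10⁴), chosen so
layer selection is testably distinct from `counts`; no biological claim is
attached. Reduction coordinates are Gaussian blobs keyed to the cell-type
label (centers at s.d. 5, within-cluster s.d. 0.7) so embeddings look like
clustered single-cell data and plots built from fetched tables are
visually meaningful. Generation pins R's generator kinds explicitly
(Mersenne-Twister / Inversion / Rejection) so a seed means the same
dataset on every platform, and restores the caller's RNG state on exit.

What the generator does **not** emulate: gene–gene covariance, realistic
library-size or batch structure, mean–variance trends, or any
correspondence between expression and the cell-type labels. Passing tests
therefore demonstrate *storage and retrieval* correctness — that every
backend returns exactly what was put in the file — not robustness to the
statistical quirks of real data, which a pure data-access layer never
interprets anyway.

`truthTable()` is the independent oracle: it resolves requests with the
same grammar but reads values by direct dense indexing of the in-memory
dataset, sharing no I/O code with the backends. Cross-format equivalence,
oracle equivalence and accessor-path equivalence over randomized requests
are the package's acceptance properties (`scripts/acceptance.R`
recomputes them from scratch).

# Numerical and interface choices

* Values are surfaced at the precision stored in the file; the fixture
  writers store float64, and cross-format comparisons in the suite use a
  1e-6 relative tolerance so float32 sources would also pass.
* User-facing dimension indices and positional cell selectors are
  1-based, as everywhere in R; on-disk sparse indices are 0-based and
  stay 0-based internally (`sparseColumn()` follows the on-disk
  convention, documented at the function).
* Row order: native dataset order when no cell selector is given,
  selector order otherwise — this makes subsetting compose predictably.
  An unknown cell ID is an error naming the first miss, not a dropped
  row.
* Categorical metadata is returned as character vectors, not factors:
  factor level order is a format-dependent artifact, and label vectors
  compare identically across formats. `uniqueValues()` returns distinct
  values in first-appearance order for the same reason.
* Duplicate cell IDs in a source are an integrity error at open. Nothing
  downstream (row labels, selectors) is well-defined with duplicated
  barcodes, so the package refuses early rather than guessing.
* Degenerate cases: a zero-column table keeps its row count; a dataset
  with zero cells yields empty ID vectors; an empty cell selector to the
  oracle is rejected as a degenerate request.

# Problem sizes in the suite

The default suite exercises the 200-cell fixture (all six renderings,
both access modes), 1000-case randomized property runs for the grammar
and the sparse-column primitive, and one 50,000-cell CSC file for the
backed-access cost bound — sizes chosen so the whole suite runs in well
under two minutes on one CPU while still separating O(column) from
O(matrix) access behavior.

# Known limitations

* No zarr, no remote access, and no R-serialized layouts (Seurat RDS,
  HDF5Array-saved SingleCellExperiment); those objects are better served
  in-session by their own ecosystems.
* MuData (`.h5mu`) is not read; the `mod/` convention above is a
  placeholder for multimodal h5ad and is flagged as an extension point.
* Source formats are read-only; the package writes only its own
  fixtures.
* Feature fetches from cell-major sparse storage (CSR h5ad, 10x HDF5)
  are O(nnz) scans by nature of the layout; choose CSC storage when
  single-feature access dominates.
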
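#' Fetch any mix of variables as one cell-by-variable table
#'
#' The central accessor. Each string in `vars` is classified against the
#' dataset's catalog as a metadata column, a feature (optionally prefixed
#' with a modality key, e.g. `"adt_CD117"`), or a reduction dimension
#' (reduction key plus 1-based dimension, e.g. `"UMAP_1"`), and the
#' corresponding per-cell values are assembled into a single `data.frame`
#' with one row per cell (row names are cell IDs) and one column per
#' request, in request order. Requests that cannot be resolved are
#' dropped with a warning; if nothing resolves, an error is raised.
#'
#' @param object A [SingleCellSource] from [openDataset()].
#' @param vars Character vector of variable requests.
#' @param layer Layer to read feature expression from; `NULL` uses each
#'   modality's default layer.
#' @param cells Cell selector: `NULL` for all cells in native order, a
#'   character vector of cell IDs, or a numeric vector of 1-based
#'   positions. Output rows follow selector order.
#' @param ... Passed to methods.
#' @return A `data.frame`, one row per selected cell, one column per
#'   resolved request.
#' @seealso [fetchMetadata()], [fetchReduction()], [resolveVars()]
#' @export
setGeneric("fetchData", function(object, vars, layer = NULL, cells = NULL, ...)
  standardGeneric("fetchData"))

#' Fetch metadata columns only
#'
#' A strict, fast path for cell metadata: every element of `vars` must be
#' a metadata column (feature or reduction requests are an error rather
#' than being inferred). In backed mode this never touches an expression
#' matrix, so [ioCount()] is unchanged. Output equals the corresponding
#' [fetchData()] call column for column.
#'
#' @inheritParams fetchData
#' @return A `data.frame` of metadata columns.
#' @export
setGeneric("fetchMetadata", function(object, vars, cells = NULL, ...)
  standardGeneric("fetchMetadata"))

#' Fetch reduction coordinates
#'
#' Returns the requested dimensions of a reduction as a `data.frame`
#' with columns named `<KEY>_<dim>` (e.g. `UMAP_1`, `UMAP_2`). When
#' `reduction` is `NULL` the dataset's default reduction
#' ([defaultReduction()]) is used. Equivalent to calling [fetchData()]
#' with the keyed dimension strings.
#'
#' @inheritParams fetchData
#' @param dims Integer vector of 1-based dimension indices
#'   (default `c(1, 2)`).
#' @param reduction Reduction name, or `NULL` for the default.
#' @return A `data.frame` of coordinate columns.
#' @export
setGeneric("fetchReduction", function(object, dims = c(1L, 2L),
                                      reduction = NULL, cells = NULL, ...)
  standardGeneric("fetchReduction"))

#' Pick the default reduction of a dataset
#'
#' Searches for UMAP, then t-SNE, then PCA (case-insensitive match on
#' reduction name or key) and returns the first that exists. If none of
#' the three is present but other reductions are, the first cataloged
#' reduction is returned with a warning; with no reductions at all an
#' error is raised.
#'
#' @inheritParams fetchData
#' @return The reduction name (a length-1 character).
#' @export
setGeneric("defaultReduction", function(object, ...)
  standardGeneric("defaultReduction"))

#' All cell IDs of a dataset
#'
#' @inheritParams fetchData
#' @return Character vector of cell IDs in native (storage) order.
#' @export
setGeneric("getAllCells", function(object, ...)
  standardGeneric("getAllCells"))

#' Distinct values of a metadata column
#'
#' Returns the distinct values of one metadata column in order of first
#' appearance, which is stable across storage formats.
#'
#' @inheritParams fetchData
#' @param var A single metadata column name.
#' @return Vector of distinct values, first-appearance order.
#' @export
setGeneric("uniqueValues", function(object, var, ...)
  standardGeneric("uniqueValues"))

#' Read one metadata column from a backend
#'
#' Low-level accessor behind [fetchMetadata()]: the named per-cell
#' annotation in native cell order. Categorical storage (e.g. the h5ad
#' codes/categories encoding) is decoded to labels, with the missing
#' code (-1) decoded to `NA`.
#'
#' @inheritParams fetchData
#' @param name Metadata column name.
#' @return Vector of length `nCells(object)`.
#' @export
setGeneric("metadataColumn", function(object, name, ...)
  standardGeneric("metadataColumn"))

#' Read one feature's expression vector from a backend
#'
#' Low-level accessor behind [fetchData()]: the expression of one
#' feature across all cells in native order, from the given modality and
#' layer. In backed mode only the slices the storage layout permits are
#' read (a single column slice for compressed-sparse-column storage).
#'
#' @inheritParams fetchData
#' @param modality Modality name.
#' @param layer Layer name.
#' @param feature Feature name.
#' @return Numeric vector of length `nCells(object)`.
#' @export
setGeneric("featureVector", function(object, modality, layer, feature, ...)
  standardGeneric("featureVector"))

#' Read reduction coordinate columns from a backend
#'
#' Low-level accessor behind [fetchReduction()]: the requested 1-based
#' dimensions of a reduction, in request order, named `<KEY>_<dim>`.
#'
#' @inheritParams fetchReduction
#' @return A named list of numeric vectors (one per requested dim).
#' @export
setGeneric("reductionColumns", function(object, reduction, dims, ...)
  standardGeneric("reductionColumns"))

#' Catalog and counter accessors
#'
#' `catalogOf()` returns the [DataCatalog] of a dataset handle or the
#' catalog implied by a [LogicalDataset]; `ioCount()` the number of
#' expression-matrix elements the handle has materialized from disk
#' since open; `nCells()` and `cellIds()` the cell count and IDs;
#' `modalities()`, `reductionNames()`, `metadataColumns()`,
#' `featureNames()` and `layerNames()` the corresponding inventory
#' pieces.
#'
#' @param object A [SingleCellSource], [DataCatalog] or [LogicalDataset].
#' @param ... Passed to methods.
#' @name catalog-accessors
#' @return `catalogOf()`: a [DataCatalog]; `ioCount()` and `nCells()`:
#'   an integer-like scalar; the rest: character vectors (or a named
#'   list for `featureNames()`/`layerNames()` without `modality`).
NULL

#' @rdname catalog-accessors
#' @export
setGeneric("catalogOf", function(object, ...) standardGeneric("catalogOf"))

#' @rdname catalog-accessors
#' @export
setGeneric("ioCount", function(object) standardGeneric("ioCount"))

#' @rdname catalog-accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname catalog-accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname catalog-accessors
#' @export
setGeneric("modalities", function(object) standardGeneric("modalities"))

#' @rdname catalog-accessors
#' @export
setGeneric("reductionNames", function(object) standardGeneric("reductionNames"))

#' @rdname catalog-accessors
#' @export
setGeneric("metadataColumns", function(object) standardGeneric("metadataColumns"))

#' @rdname catalog-accessors
#' @param modality Modality name; if missing, all modalities.
#' @export
setGeneric("featureNames", function(object, modality) standardGeneric("featureNames"))

#' @rdname catalog-accessors
#' @export
setGeneric("layerNames", function(object, modality) standardGeneric("layerNames"))
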
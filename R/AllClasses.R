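#' @import methods
#' @importFrom stats rnbinom rbinom rnorm runif setNames
#' @importFrom utils head read.table write.table
NULL

#' DataCatalog: the inventory of one dataset
#'
#' A `DataCatalog` records everything the request grammar can resolve
#' against: the modalities (feature spaces such as RNA and ADT) with their
#' feature and layer names, the reductions (low-dimensional embeddings)
#' with their column-name keys and dimensionalities, the cell metadata
#' columns, and the cell identifiers in native order.
#'
#' @slot modalities Character vector of modality names, default first.
#' @slot defaultModality Name of the modality searched for bare
#'   (un-keyed) feature requests.
#' @slot features Named list (one element per modality) of feature-name
#'   character vectors.
#' @slot layers Named list (one element per modality) of layer names.
#' @slot defaultLayers Named character vector giving the layer used per
#'   modality when a request does not name one.
#' @slot reductions Named list; each element is `list(key=, nDims=)`
#'   where `key` is the prefix used in column names (e.g. `"UMAP"`).
#' @slot metadataColumns Character vector of per-cell metadata columns.
#' @slot cellIds Character vector of unique cell identifiers, native order.
#' @slot nCells Number of cells; always `length(cellIds)`.
#'
#' @examples
#' ld <- makeFixture(fixtureSpec(nCells = 20, seed = 1))
#' catalogOf(ld)
#' @aliases DataCatalog
#' @export
setClass("DataCatalog", representation(
  modalities = "character",
  defaultModality = "character",
  features = "list",
  layers = "list",
  defaultLayers = "character",
  reductions = "list",
  metadataColumns = "character",
  cellIds = "character",
  nCells = "integer"
))

setValidity("DataCatalog", function(object) {
  msg <- character(0)
  if (length(object@modalities) > 0) {
    if (length(object@defaultModality) != 1 ||
        !(object@defaultModality %in% object@modalities))
      msg <- c(msg, "defaultModality must be one of modalities")
    if (!setequal(names(object@features), object@modalities))
      msg <- c(msg, "features must be named by modality")
    if (!setequal(names(object@layers), object@modalities))
      msg <- c(msg, "layers must be named by modality")
    for (m in object@modalities) {
      dl <- object@defaultLayers[[m]]
      if (is.null(dl) || !(dl %in% object@layers[[m]]))
        msg <- c(msg, sprintf("default layer of '%s' not among its layers", m))
    }
  }
  for (r in names(object@reductions)) {
    rd <- object@reductions[[r]]
    if (!is.list(rd) || is.null(rd$key) || is.null(rd$nDims) || rd$nDims < 1L)
      msg <- c(msg, sprintf("reduction '%s' needs a key and nDims >= 1", r))
  }
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, "cellIds contain duplicates")
  if (object@nCells != length(object@cellIds))
    msg <- c(msg, "nCells must equal length(cellIds)")
  if (length(msg)) msg else TRUE
})

#' ResolvedVar: one classified variable request
#'
#' The result of resolving a single request string against a
#' [DataCatalog]: either a metadata column, a feature (with modality and
#' effective layer), or one dimension of a reduction. Unused slots hold
#' `NA`.
#'
#' @slot requested The verbatim request string.
#' @slot kind One of `"metadata"`, `"feature"`, `"reduction_dim"`.
#' @slot modality,layer,featureName Feature requests only.
#' @slot reduction,dimIndex Reduction-dimension requests only;
#'   `dimIndex` is 1-based.
#' @aliases ResolvedVar
#' @export
setClass("ResolvedVar", representation(
  requested = "character",
  kind = "character",
  modality = "character",
  layer = "character",
  featureName = "character",
  reduction = "character",
  dimIndex = "integer"
), prototype(
  modality = NA_character_, layer = NA_character_,
  featureName = NA_character_, reduction = NA_character_,
  dimIndex = NA_integer_
))

setValidity("ResolvedVar", function(object) {
  k <- object@kind
  if (!(k %in% c("metadata", "feature", "reduction_dim")))
    return("kind must be metadata, feature or reduction_dim")
  if (k == "feature" && (is.na(object@modality) || is.na(object@featureName)))
    return("feature vars need modality and featureName")
  if (k == "reduction_dim" && (is.na(object@reduction) || is.na(object@dimIndex)))
    return("reduction_dim vars need reduction and dimIndex")
  if (k == "reduction_dim" && object@dimIndex < 1L)
    return("dimIndex is 1-based and must be >= 1")
  TRUE
})

#' ResolutionReport: bookkeeping for a batch of variable requests
#'
#' Produced by [resolveVars()]. Every input string lands in exactly one
#' of the three slots: `resolved` (in input order), `dropped`
#' (with a reason), or `deduplicated` (verbatim repeats of an earlier
#' request).
#'
#' @slot resolved List of [ResolvedVar] objects, input order preserved.
#' @slot dropped `data.frame` with columns `requested`, `reason`.
#' @slot deduplicated Character vector of removed repeats.
#' @aliases ResolutionReport
#' @export
setClass("ResolutionReport", representation(
  resolved = "list",
  dropped = "data.frame",
  deduplicated = "character"
))

#' SingleCellSource: format-agnostic handle to an on-disk dataset
#'
#' Virtual parent of the per-format handle classes returned by
#' [openDataset()]. A handle owns an immutable [DataCatalog], knows its
#' access mode (`"backed"` defers expression-matrix reads to each
#' request; `"in_memory"` materializes matrices once at open), and
#' carries a monotone counter of expression-matrix elements read from
#' disk (see [ioCount()]).
#'
#' @slot path Path the dataset was opened from.
#' @slot formatId One of `"h5ad"`, `"loom"`, `"tenx_mtx"`, `"tenx_h5"`.
#' @slot mode `"backed"` or `"in_memory"`.
#' @slot catalog The dataset's [DataCatalog].
#' @slot state Internal environment: cached tables, matrix layout
#'   descriptors, and the I/O counter.
#' @aliases SingleCellSource
#' @export
setClass("SingleCellSource", representation(
  "VIRTUAL",
  path = "character",
  formatId = "character",
  mode = "character",
  catalog = "DataCatalog",
  state = "environment"
))

#' @rdname SingleCellSource-subclasses
#' @aliases H5ADSource
#' @title Per-format dataset handle classes
#' @description Concrete [SingleCellSource] subclasses, one per
#'   supported storage format. Construct them with [openDataset()].
#' @export
setClass("H5ADSource", contains = "SingleCellSource")

#' @rdname SingleCellSource-subclasses
#' @aliases LoomSource
#' @export
setClass("LoomSource", contains = "SingleCellSource")

#' @rdname SingleCellSource-subclasses
#' @aliases TenxMTXSource
#' @export
setClass("TenxMTXSource", contains = "SingleCellSource")

#' @rdname SingleCellSource-subclasses
#' @aliases TenxH5Source
#' @export
setClass("TenxH5Source", contains = "SingleCellSource")

#' LogicalDataset: an in-memory ground-truth dataset
#'
#' The fully materialized form of a synthetic dataset produced by
#' [makeFixture()]: dense per-layer matrices, reduction coordinates and a
#' metadata table with every value known. It can be written to all
#' supported on-disk formats with [writeAllFormats()] and queried
#' directly with [truthTable()], independently of any backend code.
#'
#' @slot cellIds Character vector of unique cell barcodes.
#' @slot defaultModality Modality used for bare feature requests.
#' @slot features Named list of feature-name vectors per modality.
#' @slot layers Named list: `layers[[modality]][[layer]]` is a dense
#'   features-by-cells matrix.
#' @slot reductions Named list of `list(key=, coords=)`; `coords` is a
#'   cells-by-dims matrix.
#' @slot metadata `data.frame` of per-cell annotations, rows in cell order.
#' @aliases LogicalDataset
#' @export
setClass("LogicalDataset", representation(
  cellIds = "character",
  defaultModality = "character",
  features = "list",
  layers = "list",
  reductions = "list",
  metadata = "data.frame"
))

setValidity("LogicalDataset", function(object) {
  n <- length(object@cellIds)
  msg <- character(0)
  if (anyDuplicated(object@cellIds)) msg <- c(msg, "duplicate cell ids")
  for (m in names(object@layers)) {
    for (l in names(object@layers[[m]])) {
      mat <- object@layers[[m]][[l]]
      if (ncol(mat) != n)
        msg <- c(msg, sprintf("layer %s/%s has %d columns, expected %d cells",
                              m, l, ncol(mat), n))
      if (!all(is.finite(mat)))
        msg <- c(msg, sprintf("layer %s/%s has non-finite values", m, l))
      if (!identical(rownames(mat), object@features[[m]]))
        msg <- c(msg, sprintf("layer %s/%s rownames disagree with features", m, l))
    }
  }
  for (r in names(object@reductions)) {
    if (nrow(object@reductions[[r]]$coords) != n)
      msg <- c(msg, sprintf("reduction %s row count != n cells", r))
  }
  if (nrow(object@metadata) != n)
    msg <- c(msg, "metadata row count != n cells")
  if (length(msg)) msg else TRUE
})
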
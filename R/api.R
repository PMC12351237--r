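# The format-agnostic accessor surface. Everything funnels through the
# per-backend low-level reads plus assembleCellTable(), so all formats
# share one output contract.

#' @rdname metadataColumn
#' @export
setMethod("metadataColumn", "SingleCellSource", function(object, name, ...) {
  if (length(name) != 1L || !(name %in% object@catalog@metadataColumns))
    stop(sprintf("'%s' is not a metadata column (available: %s)",
                 paste(name, collapse = ","),
                 paste(object@catalog@metadataColumns, collapse = ", ")),
         call. = FALSE)
  object@state$meta[[name]]
})

#' @rdname featureVector
#' @export
setMethod("featureVector", "SingleCellSource",
          function(object, modality, layer, feature, ...) {
  catalog <- object@catalog
  .checkModality(catalog, modality)
  if (!(layer %in% catalog@layers[[modality]]))
    stop(sprintf("layer '%s' not found in modality '%s' (available: %s)",
                 layer, modality,
                 paste(catalog@layers[[modality]], collapse = ", ")),
         call. = FALSE)
  fidx <- match(feature, catalog@features[[modality]])
  if (is.na(fidx))
    stop(sprintf("feature '%s' not found in modality '%s'", feature, modality),
         call. = FALSE)
  mats <- object@state$mats
  if (!is.null(mats) && !is.null(mats[[modality]][[layer]]))
    return(as.numeric(mats[[modality]][[layer]][fidx, ]))
  .readFeature(object, modality, layer, fidx)
})

#' @rdname reductionColumns
#' @export
setMethod("reductionColumns", "SingleCellSource",
          function(object, reduction, dims, ...) {
  rd <- .reductionDims(object@catalog, reduction)
  dims <- as.integer(dims)
  if (!length(dims) || anyNA(dims) || min(dims) < 1L || max(dims) > rd$nDims)
    stop(sprintf("dims out of range: reduction '%s' has %d dims",
                 reduction, rd$nDims), call. = FALSE)
  coords <- object@state$reductions[[reduction]]$coords
  out <- lapply(dims, function(d) as.numeric(coords[, d]))
  names(out) <- paste0(rd$key, "_", dims)
  out
})

# one resolved var -> (name, vector) in native cell order
.pullColumn <- function(object, rv) {
  switch(rv@kind,
    metadata = metadataColumn(object, rv@requested),
    feature = featureVector(object, rv@modality, rv@layer, rv@featureName),
    reduction_dim = reductionColumns(object, rv@reduction, rv@dimIndex)[[1]])
}

#' @rdname fetchData
#' @export
setMethod("fetchData", "SingleCellSource",
          function(object, vars, layer = NULL, cells = NULL, ...) {
  report <- resolveVars(vars, object@catalog, layer)
  if (nrow(report@dropped))
    .report(sprintf("dropped unresolvable vars: %s",
                    paste(sprintf("'%s' (%s)", report@dropped$requested,
                                  report@dropped$reason), collapse = "; ")))
  cols <- lapply(report@resolved, .pullColumn, object = object)
  names(cols) <- vapply(report@resolved, function(rv) rv@requested, character(1))
  tab <- assembleCellTable(cols, object@catalog@cellIds)
  subsetCells(tab, cells)
})

#' @rdname fetchMetadata
#' @export
setMethod("fetchMetadata", "SingleCellSource",
          function(object, vars, cells = NULL, ...) {
  if (!is.character(vars) || !length(vars))
    stop("vars must be a non-empty character vector", call. = FALSE)
  bad <- setdiff(unique(vars), object@catalog@metadataColumns)
  if (length(bad))
    stop(sprintf("not a metadata column: %s",
                 paste(sprintf("'%s'", bad), collapse = ", ")), call. = FALSE)
  keep <- vars[!duplicated(vars)]
  cols <- lapply(keep, function(v) metadataColumn(object, v))
  names(cols) <- keep
  tab <- assembleCellTable(cols, object@catalog@cellIds)
  subsetCells(tab, cells)
})

#' @rdname fetchReduction
#' @export
setMethod("fetchReduction", "SingleCellSource",
          function(object, dims = c(1L, 2L), reduction = NULL, cells = NULL, ...) {
  if (!length(dims)) stop("dims must be non-empty", call. = FALSE)
  if (is.null(reduction)) reduction <- defaultReduction(object)
  cols <- reductionColumns(object, reduction, dims)
  tab <- assembleCellTable(cols, object@catalog@cellIds)
  subsetCells(tab, cells)
})

#' @rdname defaultReduction
#' @export
setMethod("defaultReduction", "SingleCellSource", function(object, ...) {
  reds <- object@catalog@reductions
  if (!length(reds))
    stop("no reductions available", call. = FALSE)
  nms <- names(reds)
  keys <- vapply(reds, function(r) r$key, character(1))
  for (want in c("umap", "tsne", "pca")) {
    hit <- which(tolower(nms) == want | tolower(keys) == want)
    if (length(hit)) return(nms[[hit[[1]]]])
  }
  .report(sprintf(
    "no UMAP, t-SNE or PCA reduction found; falling back to '%s'", nms[[1]]))
  nms[[1]]
})

#' @rdname getAllCells
#' @export
setMethod("getAllCells", "SingleCellSource", function(object, ...)
  object@catalog@cellIds)

#' @rdname uniqueValues
#' @export
setMethod("uniqueValues", "SingleCellSource", function(object, var, ...) {
  v <- metadataColumn(object, var)
  v[!duplicated(v)]
})
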
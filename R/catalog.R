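#' Construct a DataCatalog
#'
#' Builds and validates the inventory object the request grammar
#' resolves against. Backends call this at open time; it is exported so
#' synthetic catalogs can be built directly in tests and examples.
#'
#' @param modalities Character vector of modality names; the first is
#'   the default unless `defaultModality` says otherwise.
#' @param features Named list of feature-name vectors per modality.
#' @param layers Named list of layer-name vectors per modality.
#' @param defaultLayers Named character vector, default layer per
#'   modality. If missing, per modality: `"data"` if present, else
#'   `"counts"`, else the first layer.
#' @param reductions Named list of `list(key=, nDims=)` entries; a bare
#'   integer entry is promoted with `key = toupper(name)`.
#' @param metadataColumns Character vector of metadata column names.
#' @param cellIds Character vector of unique cell IDs.
#' @param defaultModality Name of the default modality.
#' @return A [DataCatalog].
#' @examples
#' cat <- dataCatalog(
#'   modalities = c("rna", "adt"),
#'   features = list(rna = c("CD34", "HLA_DRA"), adt = "CD117"),
#'   layers = list(rna = c("counts", "data"), adt = c("counts", "data")),
#'   reductions = list(umap = 2, pca = 10),
#'   metadataColumns = "cell_type",
#'   cellIds = c("c1", "c2")
#' )
#' cat
#' @export
dataCatalog <- function(modalities = character(0),
                        features = list(),
                        layers = list(),
                        defaultLayers = NULL,
                        reductions = list(),
                        metadataColumns = character(0),
                        cellIds = character(0),
                        defaultModality = if (length(modalities)) modalities[[1]] else character(0)) {
  reductions <- lapply(reductions, function(rd) {
    if (is.numeric(rd)) list(key = NULL, nDims = as.integer(rd)) else rd
  })
  for (r in names(reductions)) {
    if (is.null(reductions[[r]]$key)) reductions[[r]]$key <- toupper(r)
    reductions[[r]]$nDims <- as.integer(reductions[[r]]$nDims)
  }
  if (is.null(defaultLayers)) {
    defaultLayers <- vapply(modalities, function(m) {
      ly <- layers[[m]]
      if ("data" %in% ly) "data" else if ("counts" %in% ly) "counts" else ly[[1]]
    }, character(1))
  }
  new("DataCatalog",
      modalities = as.character(modalities),
      defaultModality = as.character(defaultModality),
      features = features[modalities],
      layers = layers[modalities],
      defaultLayers = defaultLayers,
      reductions = reductions,
      metadataColumns = as.character(metadataColumns),
      cellIds = as.character(cellIds),
      nCells = length(cellIds))
}

#' @rdname catalog-accessors
#' @export
setMethod("catalogOf", "SingleCellSource", function(object, ...) object@catalog)

#' @rdname catalog-accessors
#' @export
setMethod("nCells", "DataCatalog", function(object) object@nCells)

#' @rdname catalog-accessors
#' @export
setMethod("nCells", "SingleCellSource", function(object) object@catalog@nCells)

#' @rdname catalog-accessors
#' @export
setMethod("cellIds", "DataCatalog", function(object) object@cellIds)

#' @rdname catalog-accessors
#' @export
setMethod("cellIds", "SingleCellSource", function(object) object@catalog@cellIds)

#' @rdname catalog-accessors
#' @export
setMethod("modalities", "DataCatalog", function(object) object@modalities)

#' @rdname catalog-accessors
#' @export
setMethod("modalities", "SingleCellSource", function(object) object@catalog@modalities)

#' @rdname catalog-accessors
#' @export
setMethod("reductionNames", "DataCatalog", function(object) names(object@reductions))

#' @rdname catalog-accessors
#' @export
setMethod("reductionNames", "SingleCellSource",
          function(object) names(object@catalog@reductions))

#' @rdname catalog-accessors
#' @export
setMethod("metadataColumns", "DataCatalog", function(object) object@metadataColumns)

#' @rdname catalog-accessors
#' @export
setMethod("metadataColumns", "SingleCellSource",
          function(object) object@catalog@metadataColumns)

#' @rdname catalog-accessors
#' @export
setMethod("featureNames", "DataCatalog", function(object, modality) {
  if (missing(modality)) return(object@features)
  .checkModality(object, modality)
  object@features[[modality]]
})

#' @rdname catalog-accessors
#' @export
setMethod("featureNames", "SingleCellSource", function(object, modality) {
  if (missing(modality)) featureNames(object@catalog)
  else featureNames(object@catalog, modality)
})

#' @rdname catalog-accessors
#' @export
setMethod("layerNames", "DataCatalog", function(object, modality) {
  if (missing(modality)) return(object@layers)
  .checkModality(object, modality)
  object@layers[[modality]]
})

#' @rdname catalog-accessors
#' @export
setMethod("layerNames", "SingleCellSource", function(object, modality) {
  if (missing(modality)) layerNames(object@catalog)
  else layerNames(object@catalog, modality)
})

#' @rdname catalog-accessors
#' @export
setMethod("ioCount", "SingleCellSource", function(object) object@state$io)

.checkModality <- function(catalog, modality) {
  if (!(modality %in% catalog@modalities))
    stop(sprintf("unknown modality '%s' (available: %s)", modality,
                 paste(catalog@modalities, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# dimensionality of one cataloged reduction
.reductionDims <- function(catalog, reduction) {
  rd <- catalog@reductions[[reduction]]
  if (is.null(rd))
    stop(sprintf("unknown reduction '%s' (available: %s)", reduction,
                 paste(names(catalog@reductions), collapse = ", ")), call. = FALSE)
  rd
}

setMethod("show", "DataCatalog", function(object) {
  cat(sprintf("DataCatalog: %d cells\n", object@nCells))
  for (m in object@modalities) {
    tag <- if (identical(m, object@defaultModality)) " (default)" else ""
    cat(sprintf("  modality %s%s: %d features; layers: %s [default %s]\n",
                m, tag, length(object@features[[m]]),
                paste(object@layers[[m]], collapse = ", "),
                object@defaultLayers[[m]]))
  }
  if (length(object@reductions)) {
    rds <- vapply(names(object@reductions), function(r)
      sprintf("%s (key %s, %d dims)", r, object@reductions[[r]]$key,
              object@reductions[[r]]$nDims), character(1))
    cat("  reductions:", paste(rds, collapse = "; "), "\n")
  } else cat("  reductions: none\n")
  cat(sprintf("  metadata columns: %s\n",
              if (length(object@metadataColumns))
                paste(object@metadataColumns, collapse = ", ") else "none"))
  invisible(object)
})

setMethod("show", "SingleCellSource", function(object) {
  cat(sprintf("<%s> %s dataset, %s mode: %s\n", class(object),
              object@formatId, object@mode, object@path))
  show(object@catalog)
  cat(sprintf("  elements read: %.0f\n", object@state$io))
  invisible(object)
})

setMethod("show", "ResolvedVar", function(object) {
  extra <- switch(object@kind,
    metadata = "",
    feature = sprintf(" [%s/%s/%s]", object@modality, object@layer,
                      object@featureName),
    reduction_dim = sprintf(" [%s dim %d]", object@reduction, object@dimIndex))
  cat(sprintf("ResolvedVar '%s': %s%s\n", object@requested, object@kind, extra))
  invisible(object)
})

setMethod("show", "ResolutionReport", function(object) {
  cat(sprintf("ResolutionReport: %d resolved, %d dropped, %d deduplicated\n",
              length(object@resolved), nrow(object@dropped),
              length(object@deduplicated)))
  for (rv in object@resolved) show(rv)
  if (nrow(object@dropped))
    for (i in seq_len(nrow(object@dropped)))
      cat(sprintf("  dropped '%s': %s\n", object@dropped$requested[[i]],
                  object@dropped$reason[[i]]))
  invisible(object)
})
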
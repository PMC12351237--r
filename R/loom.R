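# loom backend.
#
# The main matrix and every layer are stored genes x cells; rhdf5 reads
# them with cells as the first R dimension, so a feature is one R
# column. row_attrs/Gene names the features and col_attrs/CellID the
# cells. loom has no dedicated reduction slot: 2-D column attributes are
# treated as reductions (key = toupper(attribute name)) and 1-D column
# attributes (other than CellID) as metadata. Layer names come from
# layers/ when present; the main matrix is exposed as layer "matrix"
# otherwise. loom carries a single modality, named "rna".

.openLoom <- function(path, mode) {
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid))
  for (req in c("matrix", "row_attrs", "col_attrs"))
    if (!.h5exists(fid, req))
      stop(sprintf("malformed loom file %s: missing '%s'", path, req),
           call. = FALSE)
  if (!.h5exists(fid, "row_attrs/Gene"))
    stop(sprintf("malformed loom file %s: missing 'row_attrs/Gene'", path),
         call. = FALSE)
  if (!.h5exists(fid, "col_attrs/CellID"))
    stop(sprintf("malformed loom file %s: missing 'col_attrs/CellID'", path),
         call. = FALSE)

  features <- as.character(rhdf5::h5read(fid, "row_attrs/Gene"))
  ids <- .checkCellIds(as.character(rhdf5::h5read(fid, "col_attrs/CellID")),
                       path)
  nCells <- length(ids)

  meta <- list()
  reductions <- list()
  for (k in setdiff(.h5children(fid, "col_attrs"), "CellID")) {
    p <- paste0("col_attrs/", k)
    d <- .h5dims(fid, p)
    if (length(d) == 1L) {
      v <- rhdf5::h5read(fid, p)
      meta[[k]] <- if (is.character(v)) as.character(v)
                   else as.numeric(as.vector(v))
    } else {
      coords <- rhdf5::h5read(fid, p)       # R: (dims, cells)
      storage.mode(coords) <- "double"
      reductions[[tolower(k)]] <- list(key = toupper(k), coords = t(coords))
    }
  }

  layout <- list()
  if (.h5exists(fid, "layers") && length(kids <- .h5children(fid, "layers"))) {
    for (k in kids) layout[[k]] <- list(path = paste0("layers/", k))
  } else {
    layout[["matrix"]] <- list(path = "matrix")
  }

  state <- .newState()
  state$meta <- meta
  state$reductions <- reductions
  state$layout <- list(rna = layout)
  if (mode == "in_memory") {
    state$mats <- list(rna = lapply(layout, function(lay) {
      m <- rhdf5::h5read(fid, lay$path)   # R: (cells, genes)
      storage.mode(m) <- "double"
      state$io <- state$io + length(m)
      m <- t(m)
      rownames(m) <- features
      m
    }))
  }

  catalog <- dataCatalog(
    modalities = "rna",
    features = list(rna = features),
    layers = list(rna = names(layout)),
    reductions = lapply(reductions, function(r)
      list(key = r$key, nDims = ncol(r$coords))),
    metadataColumns = names(meta),
    cellIds = ids,
    defaultModality = "rna")

  new("LoomSource", path = path, formatId = "loom", mode = mode,
      catalog = catalog, state = state)
}

setMethod(".readFeature", "LoomSource", function(object, modality, layer, fidx) {
  lay <- object@state$layout[[modality]][[layer]]
  fid <- rhdf5::H5Fopen(object@path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid))
  v <- as.numeric(rhdf5::h5read(fid, lay$path, index = list(NULL, fidx)))
  object@state$io <- object@state$io + length(v)
  v
})
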
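# h5ad (AnnData on-disk) backend.
#
# Catalog mapping: the main matrix (X, var, layers/) is the "rna"
# modality. Plain h5ad has no standard slot for additional modalities, so
# extra modalities are read from top-level "mod/<name>" groups (the
# MuData-style layout this package also writes); without them the file is
# single-modality. Layer names come from layers/ when present, otherwise
# the main matrix is exposed as the single layer "X". obsm entries named
# "X_<name>" (or bare "<name>") become reductions with key toupper(name).

# R-order dims of a dataset (as h5read would return them)
.h5dims <- function(fid, path) {
  did <- rhdf5::H5Dopen(fid, path)
  on.exit(rhdf5::H5Dclose(did))
  sid <- rhdf5::H5Dget_space(did)
  on.exit(rhdf5::H5Sclose(sid), add = TRUE)
  rhdf5::H5Sget_simple_extent_dims(sid)$size
}

.h5children <- function(fid, path) {
  gid <- rhdf5::H5Gopen(fid, path)
  on.exit(rhdf5::H5Gclose(gid))
  rhdf5::h5ls(gid, recursive = FALSE)$name
}

.h5isGroup <- function(fid, path) {
  oid <- rhdf5::H5Oopen(fid, path)
  on.exit(rhdf5::H5Oclose(oid))
  rhdf5::H5Iget_type(oid) == "H5I_GROUP"
}

# encoding + logical (n_obs, n_var) shape of a matrix element
.h5adMatrixInfo <- function(fid, path) {
  enc <- as.character(.h5attrOr(fid, path, "encoding-type", ""))
  if (enc %in% c("csr_matrix", "csc_matrix")) {
    shape <- as.integer(.h5attrOr(fid, path, "shape"))
    return(list(enc = sub("_matrix", "", enc), shapeObsVar = shape))
  }
  if (.h5isGroup(fid, path)) {
    # sparse group without encoding attrs: infer order from indptr length
    shape <- as.integer(.h5attrOr(fid, path, "shape"))
    if (is.null(shape) || !length(shape))
      stop(sprintf("malformed h5ad: sparse group '%s' lacks a shape attribute",
                   path), call. = FALSE)
    np <- .h5dims(fid, paste0(path, "/indptr"))
    ord <- if (np == shape[[1]] + 1L) "csr" else "csc"
    return(list(enc = ord, shapeObsVar = shape))
  }
  d <- .h5dims(fid, path)              # R order: (n_var, n_obs)
  list(enc = "dense", shapeObsVar = rev(d))
}

# decode one column of an AnnData dataframe group
.h5adColumn <- function(fid, path) {
  if (.h5isGroup(fid, path)) {
    enc <- as.character(.h5attrOr(fid, path, "encoding-type", ""))
    if (identical(enc, "categorical") ||
        .h5exists(fid, paste0(path, "/codes"))) {
      codes <- as.integer(rhdf5::h5read(fid, paste0(path, "/codes")))
      cats <- as.character(rhdf5::h5read(fid, paste0(path, "/categories")))
      out <- rep(NA_character_, length(codes))
      ok <- codes >= 0L
      out[ok] <- cats[codes[ok] + 1L]
      return(out)
    }
    stop(sprintf("unsupported column encoding at '%s'", path), call. = FALSE)
  }
  v <- rhdf5::h5read(fid, path)
  if (is.character(v)) as.character(v)
  else if (is.integer(v)) as.integer(v)
  else as.numeric(as.vector(v))
}

.h5adDataframe <- function(fid, path) {
  idxName <- as.character(.h5attrOr(fid, path, "_index", "_index"))
  index <- as.character(rhdf5::h5read(fid, paste0(path, "/", idxName)))
  colOrder <- .h5attrOr(fid, path, "column-order", character(0))
  colOrder <- as.character(colOrder)
  cols <- lapply(colOrder, function(cn) .h5adColumn(fid, paste0(path, "/", cn)))
  names(cols) <- colOrder
  list(index = index, columns = cols)
}

# one modality rooted at `base` ("" for the main matrix, "mod/<name>"
# for extra modalities)
.h5adModality <- function(fid, base) {
  pfx <- if (nzchar(base)) paste0(base, "/") else ""
  varPath <- paste0(pfx, "var")
  if (!.h5exists(fid, varPath))
    stop(sprintf("malformed h5ad: missing '%s'", varPath), call. = FALSE)
  features <- .h5adDataframe(fid, varPath)$index
  layersPath <- paste0(pfx, "layers")
  layout <- list()
  if (.h5exists(fid, layersPath) &&
      length(kids <- .h5children(fid, layersPath))) {
    for (k in kids) {
      p <- paste0(layersPath, "/", k)
      layout[[k]] <- c(list(path = p), .h5adMatrixInfo(fid, p))
    }
  } else {
    p <- paste0(pfx, "X")
    layout[["X"]] <- c(list(path = p), .h5adMatrixInfo(fid, p))
  }
  list(features = features, layout = layout)
}

.openH5AD <- function(path, mode) {
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid))
  for (req in c("obs", "var", "X"))
    if (!.h5exists(fid, req))
      stop(sprintf("malformed h5ad file %s: missing '%s'", path, req),
           call. = FALSE)

  obs <- .h5adDataframe(fid, "obs")
  ids <- .checkCellIds(obs$index, path)
  nCells <- length(ids)

  mods <- list(rna = .h5adModality(fid, ""))
  if (.h5exists(fid, "mod"))
    for (m in .h5children(fid, "mod"))
      mods[[m]] <- .h5adModality(fid, paste0("mod/", m))

  reductions <- list()
  if (.h5exists(fid, "obsm")) {
    for (k in .h5children(fid, "obsm")) {
      nm <- tolower(sub("^X_", "", k))
      coords <- rhdf5::h5read(fid, paste0("obsm/", k))  # R: (dims, cells)
      storage.mode(coords) <- "double"
      reductions[[nm]] <- list(key = toupper(nm), coords = t(coords))
    }
  }

  state <- .newState()
  state$meta <- obs$columns
  state$reductions <- reductions
  state$layout <- lapply(mods, `[[`, "layout")
  if (mode == "in_memory") {
    state$mats <- lapply(mods, function(mod) {
      ms <- lapply(mod$layout, function(lay) {
        state$io <- state$io +
          .h5MatrixStoredElements(fid, lay$path, lay$enc, lay$shapeObsVar)
        m <- .h5readMatrixObsVar(fid, lay$path, lay$enc, lay$shapeObsVar)
        rownames(m) <- mod$features
        m
      })
      ms
    })
  }

  catalog <- dataCatalog(
    modalities = names(mods),
    features = lapply(mods, `[[`, "features"),
    layers = lapply(mods, function(m) names(m$layout)),
    reductions = lapply(reductions, function(r)
      list(key = r$key, nDims = ncol(r$coords))),
    metadataColumns = names(obs$columns),
    cellIds = ids,
    defaultModality = "rna")

  new("H5ADSource", path = path, formatId = "h5ad", mode = mode,
      catalog = catalog, state = state)
}

# internal: backed read of one feature across all cells
setGeneric(".readFeature", function(object, modality, layer, fidx)
  standardGeneric(".readFeature"))

setMethod(".readFeature", "H5ADSource", function(object, modality, layer, fidx) {
  lay <- object@state$layout[[modality]][[layer]]
  fid <- rhdf5::H5Fopen(object@path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid))
  nObs <- lay$shapeObsVar[[1]]
  switch(lay$enc,
    csc = .backedMajorSlice(fid, lay$path, fidx - 1L, nObs, object@state),
    csr = .backedMinorScan(fid, lay$path, fidx - 1L, nObs, object@state),
    dense = {
      v <- as.numeric(rhdf5::h5read(fid, lay$path, index = list(fidx, NULL)))
      object@state$io <- object@state$io + nObs
      v
    })
})
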
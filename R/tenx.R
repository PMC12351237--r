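# 10x Genomics backends: Matrix Market directory and feature-barcode
# HDF5 (CellRanger v3 layout). Both carry a single modality ("rna") with
# the single layer "counts", no reductions, and no metadata beyond the
# barcodes, which serve as cell IDs. Feature names are the feature IDs
# (first column of features.tsv / matrix/features/id); duplicated names
# are disambiguated with ".1", ".2", ... suffixes in file order.

.tenxFile <- function(dir, base) {
  for (cand in c(file.path(dir, paste0(base, ".gz")), file.path(dir, base)))
    if (file.exists(cand)) return(cand)
  NA_character_
}

.readTsvColumn <- function(path, col = 1L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  tab <- read.table(con, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character")
  tab[[min(col, ncol(tab))]]
}

.tenxCatalog <- function(features, ids) {
  dataCatalog(
    modalities = "rna",
    features = list(rna = features),
    layers = list(rna = "counts"),
    reductions = list(),
    metadataColumns = character(0),
    cellIds = ids,
    defaultModality = "rna")
}

.openTenxMTX <- function(path, mode) {
  mtx <- .tenxFile(path, "matrix.mtx")
  bc <- .tenxFile(path, "barcodes.tsv")
  feat <- .tenxFile(path, "features.tsv")
  if (is.na(feat)) feat <- .tenxFile(path, "genes.tsv")
  if (is.na(mtx) || is.na(bc) || is.na(feat))
    stop(sprintf(
      "malformed 10x directory %s: needs matrix.mtx[.gz], barcodes.tsv[.gz], features.tsv[.gz]",
      path), call. = FALSE)

  con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else file(mtx)
  m <- methods::as(Matrix::readMM(con), "CsparseMatrix")  # features x cells
  features <- make.unique(.readTsvColumn(feat, 1L), sep = ".")
  ids <- .checkCellIds(.readTsvColumn(bc, 1L), path)
  if (nrow(m) != length(features) || ncol(m) != length(ids))
    stop(sprintf("malformed 10x directory %s: matrix is %d x %d but %d features and %d barcodes listed",
                 path, nrow(m), ncol(m), length(features), length(ids)),
         call. = FALSE)
  rownames(m) <- features

  # Matrix Market has no sliceable on-disk layout: materialized at open
  # in either mode.
  state <- .newState()
  state$meta <- list()
  state$reductions <- list()
  state$mats <- list(rna = list(counts = m))
  state$io <- 2 * length(m@x) + length(m@p)

  new("TenxMTXSource", path = path, formatId = "tenx_mtx", mode = mode,
      catalog = .tenxCatalog(features, ids), state = state)
}

.openTenxH5 <- function(path, mode) {
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid))
  for (req in c("matrix/shape", "matrix/data", "matrix/indices",
                "matrix/indptr", "matrix/barcodes"))
    if (!.h5exists(fid, req))
      stop(sprintf("malformed 10x HDF5 file %s: missing '%s'", path, req),
           call. = FALSE)
  shape <- as.integer(rhdf5::h5read(fid, "matrix/shape"))  # (features, cells)
  featPath <- if (.h5exists(fid, "matrix/features/id")) "matrix/features/id"
              else if (.h5exists(fid, "matrix/genes")) "matrix/genes"
              else stop(sprintf("malformed 10x HDF5 file %s: missing 'matrix/features/id'",
                                path), call. = FALSE)
  features <- make.unique(as.character(rhdf5::h5read(fid, featPath)),
                          sep = ".")
  ids <- .checkCellIds(as.character(rhdf5::h5read(fid, "matrix/barcodes")),
                       path)
  if (shape[[1]] != length(features) || shape[[2]] != length(ids))
    stop(sprintf("malformed 10x HDF5 file %s: shape disagrees with features/barcodes",
                 path), call. = FALSE)

  state <- .newState()
  state$meta <- list()
  state$reductions <- list()
  state$shape <- shape
  if (mode == "in_memory") {
    data <- as.numeric(rhdf5::h5read(fid, "matrix/data"))
    indices <- as.integer(rhdf5::h5read(fid, "matrix/indices"))
    indptr <- as.integer(rhdf5::h5read(fid, "matrix/indptr"))
    state$io <- 2 * length(data) + length(indptr)
    # column-major over cells == features x cells CSC
    m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                              dims = shape, repr = "C")
    rownames(m) <- features
    state$mats <- list(rna = list(counts = m))
  }

  new("TenxH5Source", path = path, formatId = "tenx_h5", mode = mode,
      catalog = .tenxCatalog(features, ids), state = state)
}

setMethod(".readFeature", "TenxH5Source", function(object, modality, layer, fidx) {
  fid <- rhdf5::H5Fopen(object@path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid))
  # cell-major storage: slicing one feature is a minor-dimension scan
  .backedMinorScan(fid, "matrix", fidx - 1L, object@state$shape[[2]],
                   object@state)
})
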
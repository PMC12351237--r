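# Serialize a LogicalDataset to every supported on-disk format. Each
# writer emits only what its format can represent (the capability table):
# h5ad carries everything (extra modalities under MuData-style mod/
# groups); loom carries the RNA modality, metadata and reductions; the
# 10x formats carry RNA counts and barcodes only. Omissions are silent
# by design, never an error.

.gzipFile <- function(src, dst) {
  inn <- file(src, "rb"); on.exit(close(inn), add = TRUE)
  out <- gzfile(dst, "wb"); on.exit(close(out), add = TRUE)
  repeat {
    chunk <- readBin(inn, "raw", n = 2^20)
    if (!length(chunk)) break
    writeBin(chunk, out)
  }
  unlink(src)
  invisible(dst)
}

# categorical column -> AnnData categorical group (codes/categories,
# categories in first-appearance order, NA -> code -1)
.h5adWriteCategorical <- function(loc, name, values) {
  cats <- unique(values[!is.na(values)])
  codes <- match(values, cats) - 1L
  codes[is.na(codes)] <- -1L
  gid <- rhdf5::H5Gcreate(loc, name)
  on.exit(rhdf5::H5Gclose(gid))
  .h5enc(gid, "categorical", "0.2.0")
  .h5attr(gid, "ordered", 0L)
  .h5writeStrings(gid, "categories", cats, anndata = TRUE)
  rhdf5::h5write(codes, gid, "codes")
  .h5encAt(gid, "codes", "array", "0.2.0")
  invisible(NULL)
}

.h5adWriteDataframe <- function(loc, name, index, columns) {
  gid <- rhdf5::H5Gcreate(loc, name)
  on.exit(rhdf5::H5Gclose(gid))
  .h5enc(gid, "dataframe", "0.2.0")
  .h5attr(gid, "_index", "_index")
  .h5attr(gid, "column-order", as.character(names(columns)), scalar = FALSE)
  .h5writeStrings(gid, "_index", index, anndata = TRUE)
  for (cn in names(columns)) {
    v <- columns[[cn]]
    if (is.character(v) || is.factor(v))
      .h5adWriteCategorical(gid, cn, as.character(v))
    else
      .h5writeNumeric(gid, cn, as.numeric(v), anndata = TRUE)
  }
  invisible(NULL)
}

.h5adWriteMatrix <- function(loc, name, featByCell, encoding) {
  if (encoding == "dense")
    .h5writeDenseObsVar(loc, name, featByCell, anndata = TRUE)
  else
    .h5writeSparseObsVar(loc, name, featByCell, order = encoding,
                         anndata = TRUE)
  invisible(NULL)
}

.defaultLayerName <- function(layerNames) {
  if ("data" %in% layerNames) "data"
  else if ("counts" %in% layerNames) "counts"
  else layerNames[[1]]
}

.h5adWriteModality <- function(loc, base, features, lys, encoding) {
  gid <- if (nzchar(base)) rhdf5::H5Gcreate(loc, base) else loc
  if (nzchar(base)) on.exit(rhdf5::H5Gclose(gid))
  # X mirrors the default layer so the file stands alone as plain AnnData
  .h5adWriteMatrix(gid, "X", lys[[.defaultLayerName(names(lys))]], encoding)
  .h5adWriteDataframe(gid, "var", features, list())
  lg <- rhdf5::H5Gcreate(gid, "layers")
  .h5enc(lg, "dict", "0.1.0")
  for (l in names(lys)) .h5adWriteMatrix(lg, l, lys[[l]], encoding)
  rhdf5::H5Gclose(lg)
  invisible(NULL)
}

#' Write a LogicalDataset as an AnnData h5ad file
#'
#' Produces a file conforming to the AnnData on-disk specification
#' (v0.8+ element encodings), readable by Python `anndata`. The RNA
#' modality occupies X/var/layers; additional modalities are written
#' under MuData-style `mod/<name>` groups. `encoding` selects dense,
#' CSR or CSC storage for X and all layers.
#'
#' @param ld A [LogicalDataset].
#' @param path Output file path.
#' @param encoding `"dense"`, `"csr"` or `"csc"`.
#' @return `path`, invisibly.
#' @export
writeFixtureH5AD <- function(ld, path, encoding = c("dense", "csr", "csc")) {
  encoding <- match.arg(encoding)
  unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit({ rhdf5::H5Fclose(fid); rhdf5::h5closeAll() })
  .h5enc(fid, "anndata", "0.1.0")

  dm <- ld@defaultModality
  .h5adWriteModality(fid, "", ld@features[[dm]], ld@layers[[dm]], encoding)
  .h5adWriteDataframe(fid, "obs", ld@cellIds,
                      as.list(ld@metadata))

  og <- rhdf5::H5Gcreate(fid, "obsm")
  .h5enc(og, "dict", "0.1.0")
  for (r in names(ld@reductions)) {
    .h5writeNumeric(og, paste0("X_", r), t(ld@reductions[[r]]$coords),
                    anndata = TRUE)
  }
  rhdf5::H5Gclose(og)

  others <- setdiff(names(ld@layers), dm)
  if (length(others)) {
    mg <- rhdf5::H5Gcreate(fid, "mod")
    .h5enc(mg, "dict", "0.1.0")
    rhdf5::H5Gclose(mg)
    for (m in others)
      .h5adWriteModality(fid, paste0("mod/", m), ld@features[[m]],
                         ld@layers[[m]], encoding)
  }

  ug <- rhdf5::H5Gcreate(fid, "uns")
  .h5enc(ug, "dict", "0.1.0")
  rhdf5::H5Gclose(ug)
  invisible(path)
}

#' Write a LogicalDataset as a loom file
#'
#' Emits a loom v3 layout: the main genes-by-cells matrix (the default
#' RNA layer), named layers under `layers/`, feature names in
#' `row_attrs/Gene`, cell IDs in `col_attrs/CellID`, metadata columns as
#' 1-D and reduction coordinate matrices as 2-D column attributes. Only
#' the default modality is representable.
#'
#' @inheritParams writeFixtureH5AD
#' @return `path`, invisibly.
#' @export
writeFixtureLoom <- function(ld, path) {
  unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit({ rhdf5::H5Fclose(fid); rhdf5::h5closeAll() })
  .h5attr(fid, "LOOM_SPEC_VERSION", "3.0.0")

  dm <- ld@defaultModality
  lys <- ld@layers[[dm]]
  # loom main matrix is genes x cells: R memory must be (cells, genes)
  rhdf5::h5write(t(lys[[.defaultLayerName(names(lys))]]), fid, "matrix")
  lg <- rhdf5::H5Gcreate(fid, "layers")
  for (l in names(lys)) rhdf5::h5write(t(lys[[l]]), lg, l)
  rhdf5::H5Gclose(lg)

  rg <- rhdf5::H5Gcreate(fid, "row_attrs")
  .h5writeStrings(rg, "Gene", ld@features[[dm]])
  rhdf5::H5Gclose(rg)

  cg <- rhdf5::H5Gcreate(fid, "col_attrs")
  .h5writeStrings(cg, "CellID", ld@cellIds)
  for (cn in names(ld@metadata)) {
    v <- ld@metadata[[cn]]
    if (is.character(v) || is.factor(v)) .h5writeStrings(cg, cn, as.character(v))
    else rhdf5::h5write(as.numeric(v), cg, cn)
  }
  for (r in names(ld@reductions))
    rhdf5::h5write(t(ld@reductions[[r]]$coords), cg, toupper(r))
  rhdf5::H5Gclose(cg)
  invisible(path)
}

#' Write a LogicalDataset as a 10x Matrix Market directory
#'
#' Emits `matrix.mtx.gz`, `barcodes.tsv.gz` and `features.tsv.gz`
#' (CellRanger v3 style, gzipped) holding the default modality's counts
#' layer. Metadata, reductions and other layers are outside this
#' format's capability and silently omitted.
#'
#' @param ld A [LogicalDataset].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixtureMTX <- function(ld, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- ld@defaultModality
  counts <- ld@layers[[dm]][["counts"]]
  if (is.null(counts)) counts <- ld@layers[[dm]][[1]]
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  tmp <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, tmp)
  .gzipFile(tmp, file.path(dir, "matrix.mtx.gz"))

  con <- gzfile(file.path(dir, "barcodes.tsv.gz"), "wt")
  writeLines(ld@cellIds, con); close(con)

  feats <- rownames(counts)
  con <- gzfile(file.path(dir, "features.tsv.gz"), "wt")
  writeLines(paste(feats, feats, "Gene Expression", sep = "\t"), con)
  close(con)
  invisible(dir)
}

#' Write a LogicalDataset as a 10x feature-barcode HDF5 file
#'
#' Emits the CellRanger v3 layout: a root `matrix` group holding the
#' default modality's counts as a cell-major compressed sparse matrix
#' (`data`/`indices`/`indptr`/`shape`), `barcodes`, and a `features`
#' group with `id`, `name`, `feature_type` and `genome`. As with the
#' Matrix Market writer, only counts and barcodes are representable.
#'
#' @inheritParams writeFixtureH5AD
#' @return `path`, invisibly.
#' @export
writeFixtureTenxH5 <- function(ld, path) {
  unlink(path)
  dm <- ld@defaultModality
  counts <- ld@layers[[dm]][["counts"]]
  if (is.null(counts)) counts <- ld@layers[[dm]][[1]]
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  feats <- rownames(counts)

  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit({ rhdf5::H5Fclose(fid); rhdf5::h5closeAll() })
  gid <- rhdf5::H5Gcreate(fid, "matrix")
  rhdf5::h5write(as.numeric(m@x), gid, "data")
  rhdf5::h5write(as.integer(m@i), gid, "indices")
  rhdf5::h5write(as.integer(m@p), gid, "indptr")
  rhdf5::h5write(as.integer(dim(m)), gid, "shape")
  .h5writeStrings(gid, "barcodes", ld@cellIds)
  fg <- rhdf5::H5Gcreate(gid, "features")
  .h5writeStrings(fg, "id", feats)
  .h5writeStrings(fg, "name", feats)
  .h5writeStrings(fg, "feature_type", rep("Gene Expression", length(feats)))
  .h5writeStrings(fg, "genome", rep("synthetic", length(feats)))
  rhdf5::H5Gclose(fg)
  rhdf5::H5Gclose(gid)
  invisible(path)
}

#' Write a LogicalDataset to every supported format
#'
#' Produces six datasets under `outDir`: three h5ad variants (dense, CSR
#' and CSC primary matrices), one loom file, one Matrix Market directory
#' and one 10x HDF5 file, each restricted to what its format can
#' represent. Every output opens with [openDataset()].
#'
#' @param ld A [LogicalDataset].
#' @param outDir Output directory (created if needed).
#' @return Named character vector of paths with names `h5ad_dense`,
#'   `h5ad_csr`, `h5ad_csc`, `loom`, `tenx_mtx`, `tenx_h5`.
#' @export
writeAllFormats <- function(ld, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    h5ad_dense = writeFixtureH5AD(ld, file.path(outDir, "fixture_dense.h5ad"),
                                  "dense"),
    h5ad_csr = writeFixtureH5AD(ld, file.path(outDir, "fixture_csr.h5ad"),
                                "csr"),
    h5ad_csc = writeFixtureH5AD(ld, file.path(outDir, "fixture_csc.h5ad"),
                                "csc"),
    loom = writeFixtureLoom(ld, file.path(outDir, "fixture.loom")),
    tenx_mtx = writeFixtureMTX(ld, file.path(outDir, "fixture_mtx")),
    tenx_h5 = writeFixtureTenxH5(ld, file.path(outDir, "fixture_tenx.h5")))
  paths
}
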
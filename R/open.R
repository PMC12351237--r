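#' Detect the on-disk format of a dataset
#'
#' Recognizes the four supported layouts: AnnData `.h5ad` files, `.loom`
#' files, 10x Genomics Matrix Market directories
#' (`matrix.mtx[.gz]` + `barcodes.tsv[.gz]` + `features.tsv[.gz]`), and
#' 10x Genomics feature-barcode HDF5 files (a root `matrix` group).
#' Detection is content-first: the HDF5 signature and internal structure
#' decide, with the file extension only as a fallback, so a mislabeled
#' file resolves by what it actually contains.
#'
#' @param path Path to a file or a Matrix Market directory.
#' @return One of `"h5ad"`, `"loom"`, `"tenx_mtx"`, `"tenx_h5"`.
#' @export
detectFormat <- function(path) {
  if (!file.exists(path))
    stop(sprintf("path does not exist: %s", path), call. = FALSE)
  if (dir.exists(path)) {
    if (any(file.exists(file.path(path, c("matrix.mtx", "matrix.mtx.gz")))))
      return("tenx_mtx")
    stop(sprintf("unsupported format: directory %s has no matrix.mtx[.gz]",
                 path), call. = FALSE)
  }
  isH5 <- suppressWarnings(try(rhdf5::H5Fis_hdf5(path), silent = TRUE))
  if (isTRUE(isH5)) {
    fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
    on.exit(rhdf5::H5Fclose(fid))
    rootEnc <- .h5attrOr(fid, "/", "encoding-type")
    if (identical(as.character(rootEnc), "anndata") ||
        (.h5exists(fid, "obs") && .h5exists(fid, "var")))
      return("h5ad")
    if (.h5exists(fid, "row_attrs") && .h5exists(fid, "col_attrs"))
      return("loom")
    if (.h5exists(fid, "matrix") && .h5exists(fid, "matrix/indptr"))
      return("tenx_h5")
    ext <- tolower(tools::file_ext(path))
    if (ext == "h5ad") return("h5ad")
    if (ext == "loom") return("loom")
    stop(sprintf("unsupported format: %s is HDF5 but matches no known layout",
                 path), call. = FALSE)
  }
  stop(sprintf("unsupported format: %s", path), call. = FALSE)
}

#' Open a single-cell dataset from disk
#'
#' Builds a [SingleCellSource] handle for any supported format (see
#' [detectFormat()]). In `"backed"` mode (the default) expression
#' matrices stay on disk and each feature request reads only the slices
#' its storage layout permits; `"in_memory"` materializes the matrices
#' once at open. Metadata tables, reduction coordinates and the
#' [DataCatalog] are always read eagerly — they are small. Matrix Market
#' directories have no sliceable layout and are materialized at open in
#' either mode.
#'
#' @param path Path to the dataset.
#' @param mode `"backed"` or `"in_memory"`.
#' @return A [SingleCellSource] subclass instance.
#' @examples
#' ld <- makeFixture(fixtureSpec(nCells = 30, seed = 1))
#' paths <- writeAllFormats(ld, tempfile("fx"))
#' ds <- openDataset(paths[["h5ad_csc"]], mode = "backed")
#' ds
#' fetchData(ds, c("cell_type", "CD34", "UMAP_1"))[1:3, ]
#' @export
openDataset <- function(path, mode = c("backed", "in_memory")) {
  mode <- match.arg(mode)
  fmt <- detectFormat(path)
  switch(fmt,
         h5ad = .openH5AD(path, mode),
         loom = .openLoom(path, mode),
         tenx_mtx = .openTenxMTX(path, mode),
         tenx_h5 = .openTenxH5(path, mode))
}

.checkCellIds <- function(ids, path) {
  if (anyDuplicated(ids))
    stop(sprintf("integrity error: duplicated cell ID '%s' in %s",
                 ids[duplicated(ids)][[1]], path), call. = FALSE)
  invisible(ids)
}

.newState <- function() {
  e <- new.env(parent = emptyenv())
  e$io <- 0
  e
}
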
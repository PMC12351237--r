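# Low-level rhdf5 helpers shared by the fixture writers. All strings are
# written as variable-length UTF-8 so Python readers (h5py/anndata) see
# ordinary object-dtype string arrays.

.h5attr <- function(obj, name, value, scalar = length(value) == 1L) {
  if (is.character(value) && length(value) == 0L) {
    # rhdf5 cannot write a zero-length string attribute directly
    tid <- rhdf5::H5Tcopy("H5T_C_S1")
    rhdf5::H5Tset_size(tid, NULL)
    rhdf5::H5Tset_cset(tid, "UTF-8")
    sid <- rhdf5::H5Screate_simple(0L)
    aid <- rhdf5::H5Acreate(obj, name, tid, sid)
    rhdf5::H5Aclose(aid)
    rhdf5::H5Sclose(sid)
    return(invisible(NULL))
  }
  if (is.character(value)) {
    rhdf5::h5writeAttribute(value, obj, name, variableLengthString = TRUE,
                            asScalar = scalar, encoding = "UTF-8")
  } else {
    rhdf5::h5writeAttribute(value, obj, name, asScalar = scalar)
  }
  invisible(NULL)
}

# AnnData element encoding markers
.h5enc <- function(obj, type, version) {
  .h5attr(obj, "encoding-type", type)
  .h5attr(obj, "encoding-version", version)
}

.h5encAt <- function(loc, path, type, version) {
  oid <- rhdf5::H5Oopen(loc, path)
  on.exit(rhdf5::H5Oclose(oid))
  .h5enc(oid, type, version)
}

.h5writeStrings <- function(loc, path, values, anndata = FALSE) {
  rhdf5::h5write(values, loc, path, variableLengthString = TRUE,
                 encoding = "UTF-8")
  if (anndata) .h5encAt(loc, path, "string-array", "0.2.0")
  invisible(NULL)
}

.h5writeNumeric <- function(loc, path, values, anndata = FALSE) {
  rhdf5::h5write(values, loc, path)
  if (anndata) .h5encAt(loc, path, "array", "0.2.0")
  invisible(NULL)
}

# Write a dense cells-by-features logical matrix `m` (features x cells in
# R memory) so Python sees shape (n_obs, n_var): rhdf5 reverses dims, so
# the R matrix is written as-is.
.h5writeDenseObsVar <- function(loc, path, featByCell, anndata = FALSE) {
  rhdf5::h5write(featByCell, loc, path)
  if (anndata) .h5encAt(loc, path, "array", "0.2.0")
  invisible(NULL)
}

# Write a features-by-cells matrix as an AnnData csr_matrix/csc_matrix
# group of logical shape (n_obs, n_var).
.h5writeSparseObsVar <- function(loc, path, featByCell, order = c("csr", "csc"),
                                 anndata = TRUE) {
  order <- match.arg(order)
  nObs <- ncol(featByCell); nVar <- nrow(featByCell)
  # dgCMatrix of the matrix whose columns are the major dimension:
  # csr over (obs, var) -> major obs -> columns = cells = featByCell cols
  cs <- if (order == "csr") {
    methods::as(methods::as(Matrix::Matrix(featByCell, sparse = TRUE),
                            "generalMatrix"), "CsparseMatrix")
  } else {
    methods::as(methods::as(Matrix::Matrix(t(featByCell), sparse = TRUE),
                            "generalMatrix"), "CsparseMatrix")
  }
  gid <- rhdf5::H5Gcreate(loc, path)
  on.exit(rhdf5::H5Gclose(gid))
  if (anndata) {
    .h5enc(gid, paste0(order, "_matrix"), "0.1.0")
    .h5attr(gid, "shape", as.integer(c(nObs, nVar)), scalar = FALSE)
  }
  .h5writeNumeric(gid, "data", as.numeric(cs@x))
  rhdf5::h5write(as.integer(cs@i), gid, "indices")
  rhdf5::h5write(as.integer(cs@p), gid, "indptr")
  invisible(NULL)
}

# Read any of dense / csr_matrix / csc_matrix at `path` into a dense
# features-by-cells matrix. `shapeObsVar` gives the logical (n_obs,
# n_var) shape for sparse groups.
.h5readMatrixObsVar <- function(fid, path, encType, shapeObsVar) {
  if (encType == "dense") {
    m <- rhdf5::h5read(fid, path)    # R dim (n_var, n_obs)
    storage.mode(m) <- "double"
    return(m)
  }
  data <- as.numeric(rhdf5::h5read(fid, paste0(path, "/data")))
  indices <- as.integer(rhdf5::h5read(fid, paste0(path, "/indices")))
  indptr <- as.integer(rhdf5::h5read(fid, paste0(path, "/indptr")))
  nObs <- shapeObsVar[[1]]; nVar <- shapeObsVar[[2]]
  if (encType == "csr") {
    # major = obs: columns of the dgCMatrix are obs -> var x obs = feat x cell
    m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                              dims = c(nVar, nObs), repr = "C")
  } else {
    m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                              dims = c(nObs, nVar), repr = "C")
    m <- Matrix::t(m)
  }
  as.matrix(m)
}

# number of stored elements behind a matrix dataset/group (for the
# in-memory materialization count)
.h5MatrixStoredElements <- function(fid, path, encType, shapeObsVar) {
  if (encType == "dense") return(prod(shapeObsVar))
  nnz <- length(rhdf5::h5read(fid, paste0(path, "/data")))
  major <- if (encType == "csr") shapeObsVar[[1]] else shapeObsVar[[2]]
  2 * nnz + major + 1
}

.h5attrOr <- function(fid, path, name, default = NULL) {
  at <- try(rhdf5::h5readAttributes(fid, path), silent = TRUE)
  if (inherits(at, "try-error") || is.null(at[[name]])) default
  else at[[name]]
}

.h5exists <- function(fid, path) rhdf5::H5Lexists(fid, path)
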
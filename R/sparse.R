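#' In-memory compressed sparse matrix triplet
#'
#' A light container mirroring the on-disk `csr_matrix`/`csc_matrix`
#' encodings: `data`, 0-based `indices`, and `indptr` boundary offsets
#' over the major dimension (rows for CSR, columns for CSC). `shape` is
#' the logical `(n_obs, n_var)` of the matrix.
#'
#' @param order `"csr"` or `"csc"`.
#' @param shape Integer pair `(n_obs, n_var)`.
#' @param data Numeric vector of stored values.
#' @param indices 0-based minor-dimension coordinates, one per value.
#' @param indptr Non-decreasing offsets, length = major dim + 1,
#'   starting at 0 and ending at `length(data)`.
#' @return A `SparseEncoding` object.
#' @examples
#' enc <- sparseEncoding("csc", c(3, 2), data = c(5, 7),
#'                       indices = c(0, 2), indptr = c(0, 1, 2))
#' sparseColumn(enc, 0)
#' @export
sparseEncoding <- function(order, shape, data, indices, indptr) {
  order <- match.arg(order, c("csr", "csc"))
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 0L))
  major <- if (order == "csr") shape[[1]] else shape[[2]]
  minor <- if (order == "csr") shape[[2]] else shape[[1]]
  data <- as.numeric(data)
  indices <- as.numeric(indices)
  indptr <- as.numeric(indptr)
  if (length(indptr) != major + 1L)
    stop(sprintf("indptr has length %d, expected major dim + 1 = %d",
                 length(indptr), major + 1L), call. = FALSE)
  if (is.unsorted(indptr))
    stop("indptr must be non-decreasing", call. = FALSE)
  if (indptr[[1]] != 0 || indptr[[length(indptr)]] != length(data))
    stop("indptr must start at 0 and end at length(data)", call. = FALSE)
  if (length(indices) != length(data))
    stop("indices and data must have equal length", call. = FALSE)
  if (length(indices) && (min(indices) < 0 || max(indices) >= minor))
    stop("indices out of minor-dimension bounds", call. = FALSE)
  structure(list(order = order, shape = shape, data = data,
                 indices = indices, indptr = indptr),
            class = "SparseEncoding")
}

#' Extract one dense column from a sparse encoding
#'
#' Returns column `j` (0-based, in keeping with the on-disk index
#' convention) of the logical `(n_obs, n_var)` matrix with implicit
#' zeros filled in. For CSC storage only the column's own slice of
#' `data`/`indices` plus two `indptr` entries are touched; for CSR
#' storage a full scan of `indices` is unavoidable (O(nnz)). When an
#' `io` counter environment is supplied, it is incremented by the number
#' of stored elements materialized.
#'
#' @param enc A [sparseEncoding()].
#' @param j 0-based column index in `[0, n_var)`.
#' @param io Optional environment with a numeric field `io` to increment.
#' @return Numeric vector of length `n_obs`.
#' @export
sparseColumn <- function(enc, j, io = NULL) {
  stopifnot(inherits(enc, "SparseEncoding"))
  nObs <- enc$shape[[1]]; nVar <- enc$shape[[2]]
  if (length(j) != 1L || is.na(j) || j < 0 || j >= nVar)
    stop(sprintf("column index %s out of range [0, %d)", format(j), nVar),
         call. = FALSE)
  j <- as.integer(j)
  out <- numeric(nObs)
  if (enc$order == "csc") {
    lo <- enc$indptr[[j + 1L]]; hi <- enc$indptr[[j + 2L]]
    if (hi > lo) {
      sel <- (lo + 1L):hi
      out[enc$indices[sel] + 1L] <- enc$data[sel]
    }
    if (!is.null(io)) io$io <- io$io + 2 + 2 * (hi - lo)
  } else {
    hits <- which(enc$indices == j)
    if (length(hits)) {
      rows <- findInterval(hits - 1L, enc$indptr[-1L]) + 1L
      out[rows] <- enc$data[hits]
    }
    if (!is.null(io))
      io$io <- io$io + length(enc$indptr) + length(enc$indices) + length(hits)
  }
  out
}

# ---- backed HDF5 slice readers -------------------------------------------
# Shared by the h5ad and 10x HDF5 backends. `group` is the HDF5 group
# holding data/indices/indptr. All counting is in stored elements read.

# read elements idx (1-based) of a 1-D dataset
.h5Read1D <- function(fid, name, idx = NULL) {
  if (is.null(idx)) as.numeric(rhdf5::h5read(fid, name))
  else as.numeric(rhdf5::h5read(fid, name, index = list(idx)))
}

# Contiguous major-dimension slice: CSC column or CSR row j0 (0-based).
# Returns a dense vector over the minor dimension (length nMinor).
.backedMajorSlice <- function(fid, group, j0, nMinor, io) {
  p <- .h5Read1D(fid, paste0(group, "/indptr"), (j0 + 1L):(j0 + 2L))
  k <- p[[2]] - p[[1]]
  out <- numeric(nMinor)
  if (k > 0) {
    sel <- (p[[1]] + 1):p[[2]]
    vals <- .h5Read1D(fid, paste0(group, "/data"), sel)
    idx <- .h5Read1D(fid, paste0(group, "/indices"), sel)
    out[idx + 1L] <- vals
  }
  io$io <- io$io + 2 + 2 * k
  out
}

# Minor-dimension slice j0 (0-based) via chunked scan of indices:
# the documented O(nnz) path (CSR column, or a cell-major 10x matrix
# sliced by feature). Returns a dense vector over the major dimension.
.backedMinorScan <- function(fid, group, j0, nMajor, io, chunk = 1e6) {
  indptr <- .h5Read1D(fid, paste0(group, "/indptr"))
  nnz <- indptr[[length(indptr)]]
  out <- numeric(nMajor)
  io$io <- io$io + length(indptr)
  start <- 0
  while (start < nnz) {
    end <- min(start + chunk, nnz)
    idx <- .h5Read1D(fid, paste0(group, "/indices"), (start + 1):end)
    io$io <- io$io + (end - start)
    hits <- which(idx == j0)
    if (length(hits)) {
      pos0 <- start + hits - 1
      vals <- .h5Read1D(fid, paste0(group, "/data"), pos0 + 1)
      io$io <- io$io + length(hits)
      rows <- findInterval(pos0, indptr[-1L]) + 1L
      out[rows] <- vals
    }
    start <- end
  }
  out
}
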
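#' Assemble a cell-by-variable table
#'
#' Builds the universal output object — a `data.frame` with one row per
#' cell (row names are the cell IDs) and one column per requested
#' variable, in the order given. Column names are kept verbatim
#' (`check.names = FALSE`), so request strings like `"UMAP_1"` or
#' `"adt_CD117"` survive unchanged.
#'
#' @param columns Named list of value vectors, each of length
#'   `length(cellIds)`. May be empty, giving a zero-column table.
#' @param cellIds Character vector of unique cell IDs (row names).
#' @return A `data.frame` with `length(cellIds)` rows.
#' @examples
#' assembleCellTable(list(ct = c("T", "B")), c("c1", "c2"))
#' @export
assembleCellTable <- function(columns, cellIds) {
  cellIds <- as.character(cellIds)
  if (anyDuplicated(cellIds))
    stop(sprintf("duplicate cell ID '%s'", cellIds[duplicated(cellIds)][[1]]),
         call. = FALSE)
  nms <- names(columns)
  if (length(columns) && (is.null(nms) || any(!nzchar(nms))))
    stop("every column must be named", call. = FALSE)
  if (anyDuplicated(nms))
    stop(sprintf("duplicate column name '%s'", nms[duplicated(nms)][[1]]),
         call. = FALSE)
  for (nm in nms) {
    if (length(columns[[nm]]) != length(cellIds))
      stop(sprintf("column '%s' has length %d, expected %d cells",
                   nm, length(columns[[nm]]), length(cellIds)), call. = FALSE)
  }
  # a zero-column data.frame still needs its row count pinned
  if (!length(columns)) return(data.frame(row.names = cellIds))
  out <- data.frame(columns, row.names = cellIds, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- nms
  out
}

# Resolve a cell selector against the full ID vector, in selector order.
# NULL -> all cells, native order; character -> by ID; numeric -> 1-based
# positions.
.resolveSelector <- function(cells, allIds) {
  if (is.null(cells)) return(allIds)
  if (is.character(cells)) {
    missing <- setdiff(cells, allIds)
    if (length(missing))
      stop(sprintf("cell ID '%s' not found", missing[[1]]), call. = FALSE)
    return(cells)
  }
  if (is.numeric(cells)) {
    idx <- as.integer(cells)
    if (length(idx) && (min(idx) < 1L || max(idx) > length(allIds)))
      stop(sprintf("cell index out of range [1, %d]", length(allIds)),
           call. = FALSE)
    return(allIds[idx])
  }
  stop("cells must be NULL, a character vector of IDs, or numeric positions",
       call. = FALSE)
}

#' Subset or reorder the rows of a cell table
#'
#' Rows are returned in selector order; `cells = NULL` is the identity.
#' Columns are untouched.
#'
#' @param table A table from [assembleCellTable()] or the fetch functions.
#' @param cells Selector as in [fetchData()].
#' @return The subset `data.frame`.
#' @examples
#' t <- assembleCellTable(list(x = 1:3), c("c1", "c2", "c3"))
#' subsetCells(t, c("c3", "c1"))
#' @export
subsetCells <- function(table, cells = NULL) {
  if (is.null(cells)) return(table)
  ids <- .resolveSelector(cells, rownames(table))
  table[ids, , drop = FALSE]
}

#' Write a cell table to CSV, TSV or Parquet
#'
#' Serializes a fetched table with an explicit leading `cell` column
#' holding the row names (delimited text has no row-label concept).
#' Parquet output requires the `arrow` package.
#'
#' @param table A cell-by-variable `data.frame`.
#' @param path Output file path.
#' @param format `"csv"`, `"tsv"` or `"parquet"`; default guessed from
#'   the file extension, falling back to CSV.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(table, path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", parquet = "parquet", "csv")
  }
  format <- match.arg(format, c("csv", "tsv", "parquet"))
  flat <- data.frame(cell = rownames(table), table,
                     check.names = FALSE, stringsAsFactors = FALSE)
  rownames(flat) <- NULL
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("parquet output requires the 'arrow' package", call. = FALSE)
    arrow::write_parquet(flat, path)
  } else {
    write.table(flat, path, sep = if (format == "tsv") "\t" else ",",
                row.names = FALSE, col.names = TRUE, quote = TRUE,
                qmethod = "double")
  }
  invisible(path)
}

# Pluggable warning reporter: fetch functions route non-fatal messages
# through this so pipelines can capture them. Defaults to warning().
.reporter <- function() {
  getOption("cellfetch.reporter", default = function(msg)
    warning(msg, call. = FALSE))
}

.report <- function(msg) .reporter()(msg)
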
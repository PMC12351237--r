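# Synthetic multimodal fixture generation. The generator emulates the
# shape of a CITE-seq-style reference (an RNA modality plus an ADT
# surface-protein modality, cluster-structured embeddings, categorical
# and numeric per-cell annotations) with every value known, so backend
# output can be checked against ground truth without downloading data.

.rnaMarkerNames <- c("CD34", "CD38", "CD19", "CD3E", "CD14", "HLA_DRA",
                     "HLA_DRB1", "MPO", "ELANE", "LYZ", "NKG7", "GNLY")
.adtMarkerNames <- c("CD34", "CD117", "CD45RA", "CD90", "CD123", "CD38",
                     "CD56", "CD16", "CD19", "CD33", "CD3", "HLA_DR")

.padNames <- function(markers, n, prefix) {
  if (n <= length(markers)) return(markers[seq_len(n)])
  c(markers, sprintf("%s%03d", prefix, seq_len(n - length(markers))))
}

#' Describe a synthetic multimodal dataset
#'
#' Collects and validates the parameters of the fixture generator. The
#' defaults are a desk-scale stand-in for a multimodal bone-marrow
#' reference: 200 cells, 60 RNA features and 12 ADT (surface-protein)
#' features with `counts` and log-normalized `data` layers, UMAP/t-SNE
#' embeddings plus a 10-dimensional PCA, one cell-type and one batch
#' label, and 80% zeros in the RNA counts. Feature names include
#' realistic underscore-containing symbols (`HLA_DRA`) and names shared
#' between modalities (`CD34`), which the request grammar must handle.
#'
#' @param nCells Number of cells.
#' @param rnaFeatures,adtFeatures Feature counts per modality.
#' @param layers Named list of layer names per modality; each must be a
#'   subset of `c("counts", "data")`.
#' @param reductions Named integer vector: dimensions per reduction.
#' @param categorical Named list of `list(labels=, probs=)` specs.
#' @param numeric Named list of `list(mean=, sd=)` specs.
#' @param sparsity Fraction of RNA count entries forced to zero, in
#'   `[0, 1)`. ADT counts use half this value: surface-protein panels
#'   are much denser than RNA.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated `FixtureSpec` (a classed list).
#' @examples
#' spec <- fixtureSpec(nCells = 50, seed = 7)
#' makeFixture(spec)
#' @export
fixtureSpec <- function(nCells = 200L, rnaFeatures = 60L, adtFeatures = 12L,
                        layers = list(rna = c("counts", "data"),
                                      adt = c("counts", "data")),
                        reductions = c(umap = 2L, tsne = 2L, pca = 10L),
                        categorical = list(
                          cell_type = list(
                            labels = c("HSC", "Mono", "T", "B", "NK"),
                            probs = c(0.25, 0.25, 0.2, 0.15, 0.15)),
                          batch = list(labels = c("batch1", "batch2"),
                                       probs = c(0.6, 0.4))),
                        numeric = list(
                          quality_score = list(mean = 0.8, sd = 0.1)),
                        sparsity = 0.8, seed = 1L) {
  if (nCells < 1L || rnaFeatures < 1L)
    stop("nCells and rnaFeatures must be positive", call. = FALSE)
  if (sparsity < 0 || sparsity >= 1)
    stop("sparsity must be in [0, 1)", call. = FALSE)
  for (nm in names(categorical)) {
    cs <- categorical[[nm]]
    if (length(cs$labels) != length(cs$probs))
      stop(sprintf("categorical '%s': labels and probs differ in length", nm),
           call. = FALSE)
    if (abs(sum(cs$probs) - 1) > 1e-9)
      stop(sprintf("categorical '%s': probabilities must sum to 1", nm),
           call. = FALSE)
  }
  for (m in names(layers))
    if (!all(layers[[m]] %in% c("counts", "data")))
      stop(sprintf("modality '%s': layers must be among counts, data", m),
           call. = FALSE)
  structure(list(nCells = as.integer(nCells),
                 rnaFeatures = as.integer(rnaFeatures),
                 adtFeatures = as.integer(adtFeatures),
                 layers = layers, reductions = reductions,
                 categorical = categorical, numeric = numeric,
                 sparsity = sparsity, seed = as.integer(seed)),
            class = "FixtureSpec")
}

# sparsified overdispersed counts, features x cells
.simCounts <- function(nFeat, nCells, mu, size, sparsity) {
  n <- nFeat * nCells
  raw <- rnbinom(n, mu = mu, size = size)
  keep <- rbinom(n, 1L, 1 - sparsity)
  matrix(as.numeric(raw * keep), nrow = nFeat, ncol = nCells)
}

# log1p of depth-normalized counts (scale 1e4); a testably distinct
# "data" layer, not a biological claim
.normData <- function(counts) {
  depth <- pmax(colSums(counts), 1)
  log1p(t(t(counts) / depth) * 1e4)
}

#' Generate a synthetic multimodal dataset with known ground truth
#'
#' Draws the dataset described by a [fixtureSpec()]: negative-binomial
#' counts sparsified to the requested zero fraction, a log-normalized
#' `data` layer, reduction coordinates as per-cell-type Gaussian blobs
#' (so embeddings look like clustered single-cell data), and categorical
#' plus numeric metadata. Generation is deterministic given
#' `spec$seed`, using the Mersenne-Twister/Inversion/Rejection
#' generators explicitly for cross-platform stability.
#'
#' @param spec A [fixtureSpec()].
#' @return A [LogicalDataset].
#' @export
makeFixture <- function(spec = fixtureSpec()) {
  if (!inherits(spec, "FixtureSpec"))
    stop("spec must come from fixtureSpec()", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  n <- spec$nCells
  ids <- sprintf("cell_%06d", seq_len(n))

  meta <- list()
  for (nm in names(spec$categorical)) {
    cs <- spec$categorical[[nm]]
    meta[[nm]] <- sample(cs$labels, n, replace = TRUE, prob = cs$probs)
  }
  for (nm in names(spec$numeric)) {
    ns <- spec$numeric[[nm]]
    meta[[nm]] <- rnorm(n, ns$mean, ns$sd)
  }
  metadata <- if (length(meta))
    data.frame(meta, row.names = ids, check.names = FALSE,
               stringsAsFactors = FALSE)
  else data.frame(row.names = ids)

  features <- list(
    rna = .padNames(.rnaMarkerNames, spec$rnaFeatures, "GENE"),
    adt = .padNames(.adtMarkerNames, spec$adtFeatures, "ADT"))
  base <- list(
    rna = .simCounts(spec$rnaFeatures, n, mu = 5, size = 2, spec$sparsity),
    adt = .simCounts(spec$adtFeatures, n, mu = 30, size = 5,
                     spec$sparsity / 2))
  layers <- list()
  for (m in names(spec$layers)) {
    counts <- base[[m]]
    rownames(counts) <- features[[m]]
    lys <- list()
    for (l in spec$layers[[m]])
      lys[[l]] <- if (l == "counts") counts else .normData(counts)
    layers[[m]] <- lys
  }
  features <- features[names(layers)]

  # cluster-keyed Gaussian blobs: cells of one type share a center
  grouping <- if (length(spec$categorical)) meta[[names(spec$categorical)[[1]]]]
              else rep("all", n)
  groups <- unique(grouping)
  reductions <- list()
  for (r in names(spec$reductions)) {
    k <- as.integer(spec$reductions[[r]])
    centers <- matrix(rnorm(length(groups) * k, sd = 5), nrow = length(groups))
    coords <- centers[match(grouping, groups), , drop = FALSE] +
      matrix(rnorm(n * k, sd = 0.7), nrow = n)
    dimnames(coords) <- NULL
    reductions[[r]] <- list(key = toupper(r), coords = coords)
  }

  new("LogicalDataset", cellIds = ids, defaultModality = "rna",
      features = features, layers = layers, reductions = reductions,
      metadata = metadata)
}

#' @rdname catalog-accessors
#' @export
setMethod("catalogOf", "LogicalDataset", function(object, ...) {
  dataCatalog(
    modalities = names(object@layers),
    features = object@features,
    layers = lapply(object@layers, names),
    reductions = lapply(object@reductions, function(r)
      list(key = r$key, nDims = ncol(r$coords))),
    metadataColumns = names(object@metadata),
    cellIds = object@cellIds,
    defaultModality = object@defaultModality)
})

#' @rdname catalog-accessors
#' @export
setMethod("nCells", "LogicalDataset", function(object) length(object@cellIds))

#' @rdname catalog-accessors
#' @export
setMethod("cellIds", "LogicalDataset", function(object) object@cellIds)

setMethod("show", "LogicalDataset", function(object) {
  cat(sprintf("LogicalDataset: %d cells\n", length(object@cellIds)))
  for (m in names(object@layers))
    cat(sprintf("  %s: %d features, layers %s\n", m,
                length(object@features[[m]]),
                paste(names(object@layers[[m]]), collapse = ", ")))
  cat(sprintf("  reductions: %s\n",
              paste(names(object@reductions), collapse = ", ")))
  cat(sprintf("  metadata: %s\n",
              paste(names(object@metadata), collapse = ", ")))
  invisible(object)
})

#' Ground-truth table by direct dense indexing
#'
#' The independent oracle: resolves `vars` with the same grammar the
#' backends use, but pulls every value straight out of the in-memory
#' [LogicalDataset] matrices, touching no backend code. Backend output
#' for any format must match this table on the format's capabilities.
#'
#' @param ld A [LogicalDataset].
#' @inheritParams fetchData
#' @return A cell-by-variable `data.frame`.
#' @export
truthTable <- function(ld, vars, layer = NULL, cells = NULL) {
  stopifnot(is(ld, "LogicalDataset"))
  if (!is.null(cells) && length(cells) == 0L)
    stop("cells selector is empty", call. = FALSE)
  catalog <- catalogOf(ld)
  report <- resolveVars(vars, catalog, layer)
  if (nrow(report@dropped))
    .report(sprintf("dropped unresolvable vars: %s",
                    paste(sprintf("'%s' (%s)", report@dropped$requested,
                                  report@dropped$reason), collapse = "; ")))
  cols <- lapply(report@resolved, function(rv) {
    switch(rv@kind,
      metadata = ld@metadata[[rv@requested]],
      feature = as.numeric(ld@layers[[rv@modality]][[rv@layer]][rv@featureName, ]),
      reduction_dim = as.numeric(
        ld@reductions[[rv@reduction]]$coords[, rv@dimIndex]))
  })
  names(cols) <- vapply(report@resolved, function(rv) rv@requested, character(1))
  subsetCells(assembleCellTable(cols, ld@cellIds), cells)
}
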
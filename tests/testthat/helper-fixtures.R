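# Shared fixtures and independent oracles for the suite. The default
# 200-cell dataset and its six on-disk renderings are built once per
# session and cached.

.cache <- new.env(parent = emptyenv())

defaultFixture <- function() {
  if (is.null(.cache$ld)) .cache$ld <- makeFixture(fixtureSpec(seed = 1L))
  .cache$ld
}

defaultPaths <- function() {
  if (is.null(.cache$paths)) {
    dir <- file.path(tempdir(), "cellfetch-fixture")
    .cache$paths <- writeAllFormats(defaultFixture(), dir)
  }
  .cache$paths
}

openedHandles <- function(mode = "backed") {
  key <- paste0("handles_", mode)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- lapply(defaultPaths(), openDataset, mode = mode)
  .cache[[key]]
}

smallFixture <- function(n = 30, seed = 4, ...) {
  makeFixture(fixtureSpec(nCells = n, seed = seed, ...))
}

# hand-built catalog for grammar tests: multimodal, with collisions
grammarCatalog <- function() {
  dataCatalog(
    modalities = c("rna", "adt"),
    features = list(
      rna = c("CD34", "CD38", "HLA_DRA", "UMAP_like", "cell_type"),
      adt = c("CD34", "CD117", "HLA_DR")),
    layers = list(rna = c("counts", "data"), adt = c("counts", "data")),
    reductions = list(umap = 2, tsne = 2, pca = 10),
    metadataColumns = c("cell_type", "batch", "CD38"),
    cellIds = sprintf("c%02d", 1:5))
}

# Independent rule-by-rule classifier used to test precedence totality:
# each rule is checked on its own, then the precedence-first candidate is
# taken. Shares no code with resolveVar().
bruteClassify <- function(var, catalog, layer = NULL) {
  cands <- list()
  pos <- regexpr("_", var, fixed = TRUE)
  prefix <- if (pos > 1) substr(var, 1, pos - 1) else ""
  rest <- if (pos > 0) substr(var, pos + 1, nchar(var)) else ""
  redNames <- reductionNames(catalog)
  if (nzchar(prefix)) {
    for (r in redNames) {
      key <- catalog@reductions[[r]]$key
      if ((tolower(prefix) == tolower(r) || tolower(prefix) == tolower(key)) &&
          grepl("^[0-9]+$", rest)) {
        d <- as.integer(rest)
        if (d >= 1 && d <= catalog@reductions[[r]]$nDims)
          cands$reduction_dim <- list(kind = "reduction_dim", reduction = r,
                                      dimIndex = d)
        else
          cands$outOfRange <- TRUE
      }
    }
    for (m in modalities(catalog)) {
      if (tolower(prefix) == tolower(m) && rest %in% catalog@features[[m]])
        cands$feature_keyed <- list(kind = "feature", modality = m,
                                    featureName = rest)
    }
  }
  if (var %in% metadataColumns(catalog))
    cands$metadata <- list(kind = "metadata")
  dm <- catalog@defaultModality
  if (var %in% catalog@features[[dm]])
    cands$feature_bare <- list(kind = "feature", modality = dm,
                               featureName = var)
  if (!is.null(cands$reduction_dim)) return(cands$reduction_dim)
  if (isTRUE(cands$outOfRange)) return(list(kind = "dropped"))
  if (!is.null(cands$feature_keyed)) return(cands$feature_keyed)
  if (!is.null(cands$metadata)) return(cands$metadata)
  if (!is.null(cands$feature_bare)) return(cands$feature_bare)
  list(kind = "dropped")
}

# random catalogs + var strings for the grammar property
randomGrammarCase <- function() {
  mods <- sample(c("rna", "adt", "atac"), sample(1:3, 1))
  feats <- lapply(mods, function(m)
    sample(c("CD34", "CD117", "HLA_DRA", "GENE_X", "FOO", "umap", "pca1"),
           sample(2:5, 1)))
  names(feats) <- mods
  reds <- list()
  for (r in sample(c("umap", "tsne", "pca", "diffmap"), sample(0:3, 1)))
    reds[[r]] <- sample(1:10, 1)
  catalog <- dataCatalog(
    modalities = mods, features = feats,
    layers = setNames(rep(list(c("counts", "data")), length(mods)), mods),
    reductions = reds,
    metadataColumns = sample(c("cell_type", "batch", "CD34", "UMAP_1"),
                             sample(0:3, 1)),
    cellIds = "c1")
  pool <- c(unlist(feats, use.names = FALSE), metadataColumns(catalog),
            "UMAP_1", "umap_2", "UMAP_99", "PCA_3", "tsne_1",
            "adt_CD117", "rna_CD34", "ADT_HLA_DR", "HLA_DRA", "GENE_X",
            "adt_nope", "rna_UMAP_1", "bogus", "x_y_z", "CD34")
  list(catalog = catalog, var = sample(pool, 1))
}

# capability-aware random requests for cross-format / oracle testing.
# Returns list(vars=, layer=, cells=, formats=) where `formats` names the
# fixture outputs able to serve every feature var under `layer`.
randomRequest <- function(ld, allowSelector = TRUE) {
  catalog <- catalogOf(ld)
  allFmt <- c("h5ad_dense", "h5ad_csr", "h5ad_csc", "loom", "tenx_mtx",
              "tenx_h5")
  h5Loom <- c("h5ad_dense", "h5ad_csr", "h5ad_csc", "loom")
  h5Only <- c("h5ad_dense", "h5ad_csr", "h5ad_csc")
  layer <- sample(list(NULL, "counts", "data"), 1,
                  prob = c(0.5, 0.3, 0.2))[[1]]
  pool <- list()
  for (mc in metadataColumns(catalog))
    pool[[length(pool) + 1]] <- list(var = mc, formats = h5Loom)
  rnaFeats <- sample(featureNames(catalog, "rna"), 4)
  featFmt <- if (identical(layer, "counts")) allFmt else h5Loom
  for (f in rnaFeats) {
    pool[[length(pool) + 1]] <- list(var = f, formats = featFmt)
    pool[[length(pool) + 1]] <- list(var = paste0("rna_", f), formats = featFmt)
  }
  for (f in sample(featureNames(catalog, "adt"), 2))
    pool[[length(pool) + 1]] <- list(var = paste0("adt_", f), formats = h5Only)
  for (r in reductionNames(catalog)) {
    key <- catalog@reductions[[r]]$key
    d <- sample(catalog@reductions[[r]]$nDims, 1)
    pool[[length(pool) + 1]] <- list(var = paste0(key, "_", d),
                                     formats = h5Loom)
    pool[[length(pool) + 1]] <- list(var = paste0(r, "_", d),
                                     formats = h5Loom)
  }
  picks <- sample(pool, sample(1:4, 1))
  cells <- NULL
  if (allowSelector && runif(1) < 0.4) {
    ids <- cellIds(catalog)
    cells <- if (runif(1) < 0.5) sample(ids, sample(length(ids), 1))
             else sample(seq_along(ids), sample(length(ids), 1))
  }
  list(vars = vapply(picks, `[[`, character(1), "var"),
       layer = layer,
       cells = cells,
       formats = Reduce(intersect, lapply(picks, `[[`, "formats")))
}

expect_tables_equal <- function(got, want, tolerance = 1e-6) {
  expect_identical(dim(got), dim(want))
  expect_identical(rownames(got), rownames(want))
  expect_identical(colnames(got), colnames(want))
  for (cn in colnames(want)) {
    if (is.numeric(want[[cn]]))
      expect_equal(got[[cn]], want[[cn]], tolerance = tolerance,
                   ignore_attr = TRUE)
    else
      expect_identical(as.character(got[[cn]]), as.character(want[[cn]]))
  }
}
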
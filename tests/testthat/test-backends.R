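# Backend behavior is checked against the LogicalDataset ground truth:
# every catalog and every value a backend returns must match what the
# generator put in the file.

test_that("format detection is content-first", {
  paths <- defaultPaths()
  expect_identical(detectFormat(paths[["h5ad_csr"]]), "h5ad")
  expect_identical(detectFormat(paths[["loom"]]), "loom")
  expect_identical(detectFormat(paths[["tenx_mtx"]]), "tenx_mtx")
  expect_identical(detectFormat(paths[["tenx_h5"]]), "tenx_h5")
  empty <- tempfile(fileext = ".h5ad")
  writeLines("not hdf5", empty)
  expect_error(detectFormat(empty), "unsupported format")
  expect_error(detectFormat(tempfile()), "does not exist")
})

test_that("h5ad catalogs mirror the generated dataset and open lazily", {
  ld <- defaultFixture()
  ds <- openDataset(defaultPaths()[["h5ad_csc"]], "backed")
  cat <- catalogOf(ds)
  expect_setequal(modalities(cat), c("rna", "adt"))
  expect_setequal(reductionNames(cat), c("umap", "tsne", "pca"))
  expect_identical(cat@reductions$pca$nDims, 10L)
  expect_identical(featureNames(cat, "rna"), ld@features$rna)
  expect_identical(featureNames(cat, "adt"), ld@features$adt)
  expect_identical(metadataColumns(cat), names(ld@metadata))
  expect_identical(cellIds(cat), ld@cellIds)
  expect_identical(layerNames(cat, "rna"), c("counts", "data"))
  expect_identical(cat@defaultLayers[["rna"]], "data")
  expect_identical(ioCount(ds), 0)     # backed open reads no matrix data
})

test_that("10x formats expose counts and barcodes only", {
  for (f in c("tenx_mtx", "tenx_h5")) {
    ds <- openedHandles("backed")[[f]]
    cat <- catalogOf(ds)
    expect_identical(modalities(cat), "rna")
    expect_identical(layerNames(cat, "rna"), "counts")
    expect_length(reductionNames(cat), 0)
    expect_length(metadataColumns(cat), 0)
    expect_identical(cellIds(cat), defaultFixture()@cellIds)
  }
})

test_that("loom carries the RNA modality, metadata and 2-D reductions", {
  cat <- catalogOf(openedHandles("backed")[["loom"]])
  expect_identical(modalities(cat), "rna")
  expect_setequal(reductionNames(cat), c("umap", "tsne", "pca"))
  expect_setequal(metadataColumns(cat), names(defaultFixture()@metadata))
})

test_that("feature, metadata and reduction reads equal the ground truth", {
  ld <- defaultFixture()
  for (f in names(defaultPaths())) {
    ds <- openedHandles("backed")[[f]]
    lyr <- if (f %in% c("tenx_mtx", "tenx_h5")) "counts" else "data"
    v <- featureVector(ds, "rna", lyr, "CD34")
    expect_equal(v, as.numeric(ld@layers$rna[[lyr]]["CD34", ]),
                 tolerance = 1e-6, label = f)
    if (!(f %in% c("tenx_mtx", "tenx_h5"))) {
      expect_identical(metadataColumn(ds, "cell_type"), ld@metadata$cell_type,
                       label = f)
      expect_equal(metadataColumn(ds, "quality_score"),
                   ld@metadata$quality_score, tolerance = 1e-6)
      rc <- reductionColumns(ds, "umap", c(2L, 1L))
      expect_identical(names(rc), c("UMAP_2", "UMAP_1"))
      expect_equal(rc[[1]], as.numeric(ld@reductions$umap$coords[, 2]),
                   tolerance = 1e-6)
    }
  }
})

test_that("backed and in-memory handles return identical results", {
  vars <- c("cell_type", "CD34", "adt_CD117", "UMAP_1", "HLA_DRA")
  for (f in c("h5ad_dense", "h5ad_csr", "h5ad_csc")) {
    b <- fetchData(openedHandles("backed")[[f]], vars)
    m <- fetchData(openedHandles("in_memory")[[f]], vars)
    expect_identical(b, m, label = f)
  }
  b <- fetchData(openedHandles("backed")[["loom"]], c("cell_type", "CD34"))
  m <- fetchData(openedHandles("in_memory")[["loom"]], c("cell_type", "CD34"))
  expect_identical(b, m)
})

test_that("lookup errors name the failing level", {
  ds <- openedHandles("backed")[["h5ad_csc"]]
  expect_error(featureVector(ds, "protein", "data", "CD34"),
               "unknown modality 'protein'")
  expect_error(featureVector(ds, "rna", "nope", "CD34"),
               "layer 'nope' not found in modality 'rna'")
  expect_error(featureVector(ds, "rna", "data", "NOT_A_GENE"),
               "feature 'NOT_A_GENE' not found")
  expect_error(metadataColumn(ds, "no_such_col"), "not a metadata column")
  expect_error(reductionColumns(ds, "diffmap", 1L), "unknown reduction")
  expect_error(reductionColumns(ds, "pca", 99L), "dims out of range")
})

test_that("an all-zero feature reads back as a zero vector", {
  ld <- smallFixture(n = 15, seed = 9)
  ld@layers$rna$counts["GENE001", ] <- 0
  ld@layers$rna$data["GENE001", ] <- 0
  dir <- tempfile("zerofeat")
  for (enc in c("csr", "csc")) {
    p <- file.path(dir, paste0(enc, ".h5ad"))
    dir.create(dir, showWarnings = FALSE)
    writeFixtureH5AD(ld, p, enc)
    ds <- openDataset(p, "backed")
    expect_identical(featureVector(ds, "rna", "counts", "GENE001"),
                     rep(0, 15))
  }
})

test_that("categorical codes decode to labels with -1 as missing", {
  ld <- smallFixture(n = 10, seed = 2)
  ld@metadata$cell_type[c(3, 7)] <- NA
  p <- tempfile(fileext = ".h5ad")
  writeFixtureH5AD(ld, p, "dense")
  ds <- openDataset(p)
  got <- metadataColumn(ds, "cell_type")
  expect_identical(is.na(got), is.na(ld@metadata$cell_type))
  expect_identical(got[-c(3, 7)], ld@metadata$cell_type[-c(3, 7)])
})

test_that("malformed files raise errors naming the missing component", {
  src <- defaultPaths()[["h5ad_dense"]]
  broken <- tempfile(fileext = ".h5ad")
  file.copy(src, broken)
  fid <- rhdf5::H5Fopen(broken)
  rhdf5::H5Ldelete(fid, "obs")
  rhdf5::H5Fclose(fid)
  expect_error(openDataset(broken), "missing 'obs'")

  dir <- tempfile("notmtx")
  dir.create(dir)
  file.create(file.path(dir, "matrix.mtx"))
  expect_error(openDataset(dir), "barcodes")
})

test_that("duplicated cell barcodes are an integrity error", {
  ld <- smallFixture(n = 6, seed = 3)
  dir <- tempfile("dupmtx")
  writeFixtureMTX(ld, dir)
  bc <- file.path(dir, "barcodes.tsv.gz")
  ids <- readLines(bc)
  ids[2] <- ids[1]
  con <- gzfile(bc, "wt"); writeLines(ids, con); close(con)
  expect_error(openDataset(dir), "duplicated cell ID")
})

test_that("duplicate 10x feature names are disambiguated in file order", {
  ld <- smallFixture(n = 8, seed = 5)
  dir <- tempfile("dupfeat")
  writeFixtureMTX(ld, dir)
  ft <- file.path(dir, "features.tsv.gz")
  rows <- readLines(ft)
  rows[2] <- sub("^[^\t]+", "CD34", rows[2])   # CD34 now appears twice
  con <- gzfile(ft, "wt"); writeLines(rows, con); close(con)
  ds <- openDataset(dir)
  feats <- featureNames(ds, "rna")
  expect_identical(feats[1:2], c("CD34", "CD34.1"))
})

test_that("backed CSC h5ad reads are proportional to the column slice", {
  ld <- defaultFixture()
  ds <- openDataset(defaultPaths()[["h5ad_csc"]], "backed")
  expect_identical(ioCount(ds), 0)
  before <- ioCount(ds)
  invisible(featureVector(ds, "rna", "data", "CD34"))
  nnzCol <- sum(ld@layers$rna$data["CD34", ] != 0)
  expect_lte(ioCount(ds) - before, 2 * nnzCol + 4)
})
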
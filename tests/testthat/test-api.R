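test_that("fetchData assembles mixed requests matching the ground truth", {
  ld <- defaultFixture()
  for (f in c("h5ad_dense", "loom")) {
    ds <- openedHandles("backed")[[f]]
    vars <- c("cell_type", "CD34", "UMAP_1")
    got <- fetchData(ds, vars)
    expect_tables_equal(got, truthTable(ld, vars))
  }
})

test_that("column order echoes the post-dedup request order verbatim", {
  ds <- openedHandles("backed")[["h5ad_csr"]]
  got <- fetchData(ds, c("UMAP_2", "cell_type", "UMAP_2", "rna_CD38"))
  expect_identical(colnames(got), c("UMAP_2", "cell_type", "rna_CD38"))
})

test_that("partial misses warn and drop; total misses error", {
  ds <- openedHandles("backed")[["h5ad_dense"]]
  expect_warning(got <- fetchData(ds, c("cell_type", "bogus")), "bogus")
  expect_identical(colnames(got), "cell_type")
  expect_error(suppressWarnings(fetchData(ds, c("nope1", "nope2"))),
               "nope1")
  # on a counts-only format, a reduction request is unresolvable
  expect_error(suppressWarnings(
    fetchData(openedHandles("backed")[["tenx_mtx"]], "UMAP_1")),
    "UMAP_1")
})

test_that("the cells selector subsets and orders rows across paths", {
  ds <- openedHandles("backed")[["h5ad_csc"]]
  ids <- rev(head(getAllCells(ds), 5))
  got <- fetchData(ds, c("cell_type", "CD34"), cells = ids)
  expect_identical(rownames(got), ids)
  gotM <- fetchMetadata(ds, "cell_type", cells = ids)
  expect_identical(rownames(gotM), ids)
  gotR <- fetchReduction(ds, cells = head(getAllCells(ds), 3))
  expect_identical(nrow(gotR), 3L)
  expect_error(fetchData(ds, "CD34", cells = "ghost"), "'ghost' not found")
})

test_that("fetchMetadata is strict and equals the fetchData column", {
  ds <- openedHandles("backed")[["h5ad_dense"]]
  for (mc in metadataColumns(ds)) {
    expect_identical(fetchMetadata(ds, mc), fetchData(ds, mc), label = mc)
  }
  expect_error(fetchMetadata(ds, "CD34"), "not a metadata column")
  expect_error(fetchMetadata(ds, "UMAP_1"), "not a metadata column")
})

test_that("fetchMetadata never touches an expression matrix when backed", {
  ds <- openDataset(defaultPaths()[["h5ad_csc"]], "backed")
  invisible(fetchMetadata(ds, c("cell_type", "batch", "quality_score")))
  expect_identical(ioCount(ds), 0)
})

test_that("fetchReduction equals fetchData on the keyed var strings", {
  ds <- openedHandles("backed")[["loom"]]
  cat <- catalogOf(ds)
  for (r in reductionNames(ds)) {
    key <- cat@reductions[[r]]$key
    got <- fetchReduction(ds, dims = c(1L, 2L), reduction = r)
    want <- fetchData(ds, paste0(key, "_", 1:2))
    expect_identical(got, want, label = r)
  }
  # default dims are (1, 2) on the default reduction
  expect_identical(fetchReduction(ds), fetchData(ds, c("UMAP_1", "UMAP_2")))
  # requested dim order is preserved
  swapped <- fetchReduction(ds, dims = c(2L, 1L), reduction = "pca")
  expect_identical(colnames(swapped), c("PCA_2", "PCA_1"))
})

test_that("defaultReduction follows the UMAP, t-SNE, PCA search order", {
  mk <- function(reds) {
    ld <- makeFixture(fixtureSpec(nCells = 10, seed = 1, reductions = reds))
    openDataset(writeFixtureH5AD(ld, tempfile(fileext = ".h5ad"), "dense"))
  }
  expect_identical(defaultReduction(mk(c(umap = 2, tsne = 2, pca = 5))), "umap")
  expect_identical(defaultReduction(mk(c(tsne = 2, pca = 5))), "tsne")
  expect_identical(defaultReduction(mk(c(pca = 5))), "pca")
  expect_warning(r <- defaultReduction(mk(c(diffmap = 2))), "falling back")
  expect_identical(r, "diffmap")
  noRed <- mk(setNames(integer(0), character(0)))
  expect_error(defaultReduction(noRed), "no reductions available")
  expect_error(fetchReduction(noRed), "no reductions available")
})

test_that("getAllCells returns native-order barcodes", {
  ld <- defaultFixture()
  for (f in names(defaultPaths())) {
    ds <- openedHandles("backed")[[f]]
    expect_identical(getAllCells(ds), ld@cellIds, label = f)
    expect_length(getAllCells(ds), nCells(ds))
  }
})

test_that("uniqueValues preserves first-appearance order across formats", {
  ld <- defaultFixture()
  bruteUnique <- function(v) { seen <- character(0)
    for (x in v) if (!(x %in% seen)) seen <- c(seen, x)
    seen }
  for (f in c("h5ad_dense", "h5ad_csr", "h5ad_csc", "loom")) {
    ds <- openedHandles("backed")[[f]]
    got <- uniqueValues(ds, "cell_type")
    expect_identical(got, bruteUnique(ld@metadata$cell_type), label = f)
  }
  expect_error(uniqueValues(openedHandles("backed")[["h5ad_dense"]], "CD34"),
               "not a metadata column")
})

test_that("warnings route through the pluggable reporter", {
  ds <- openedHandles("backed")[["h5ad_dense"]]
  seen <- character(0)
  withr::with_options(
    list(cellfetch.reporter = function(msg) seen <<- c(seen, msg)),
    invisible(fetchData(ds, c("cell_type", "bogus"))))
  expect_length(seen, 1L)
  expect_match(seen, "bogus")
})

test_that("python readers agree with fetchData on a single-modality file", {
  py <- Sys.which("python")
  skip_if(py == "", "no python interpreter on PATH")
  ld <- makeFixture(fixtureSpec(nCells = 25, seed = 6,
                                layers = list(rna = c("counts", "data"))))
  p <- tempfile(fileext = ".h5ad")
  writeFixtureH5AD(ld, p, "csr")
  ds <- openDataset(p)
  tab <- fetchData(ds, c("CD34", "cell_type", "UMAP_1"), layer = "counts")
  csv <- tempfile(fileext = ".csv")
  writeCellTable(tab, csv)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, anndata, numpy as np, pandas as pd",
    "a = anndata.read_h5ad(sys.argv[1])",
    "t = pd.read_csv(sys.argv[2])",
    "x = np.asarray(a.layers['counts'][:, a.var_names.get_loc('CD34')].todense()).ravel()",
    "assert np.allclose(x, t['CD34'], atol=1e-6)",
    "assert (a.obs['cell_type'].astype(str).values == t['cell_type'].values).all()",
    "assert np.allclose(a.obsm['X_umap'][:, 0], t['UMAP_1'], atol=1e-6)",
    "assert list(a.obs_names) == list(t['cell'])",
    "print('OK')"), script)
  out <- suppressWarnings(system2(py, c(script, p, csv),
                                  stdout = TRUE, stderr = TRUE))
  expect_identical(attr(out, "status"), NULL)
  expect_true(any(grepl("OK", out)))
})
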
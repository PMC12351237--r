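# Grammar tests run against a hand-built multimodal catalog containing
# deliberate collisions: a metadata column that is also an RNA feature
# (CD38), an RNA feature named like a metadata column (cell_type), and
# underscore-containing feature names (HLA_DRA, HLA_DR).

test_that("splitKey splits only at a known key prefix", {
  cat <- grammarCatalog()
  expect_identical(splitKey("adt_CD117", cat),
                   list(key = "adt", remainder = "CD117"))
  expect_identical(splitKey("UMAP_1", cat),
                   list(key = "UMAP", remainder = "1"))
  # unknown prefix: absence, the feature name survives whole
  expect_null(splitKey("HLA_DRA", cat))
  expect_null(splitKey("CD34", cat))      # no underscore at all
  # only the first underscore is tried
  expect_identical(splitKey("rna_UMAP_1", cat),
                   list(key = "rna", remainder = "UMAP_1"))
  # key matching is case-insensitive
  expect_identical(splitKey("ADT_CD117", cat),
                   list(key = "ADT", remainder = "CD117"))
})

test_that("resolveVar classifies by the documented precedence", {
  cat <- grammarCatalog()
  rv <- resolveVar("cell_type", cat)
  expect_s4_class(rv, "ResolvedVar")
  expect_identical(rv@kind, "metadata")   # metadata beats bare rna feature

  rv <- resolveVar("CD38", cat)           # metadata column AND rna feature
  expect_identical(rv@kind, "metadata")

  rv <- resolveVar("rna_CD38", cat)       # keyed lookup bypasses metadata
  expect_identical(rv@kind, "feature")
  expect_identical(rv@featureName, "CD38")

  rv <- resolveVar("CD34", cat)           # in both modalities: default wins
  expect_identical(rv@modality, "rna")

  rv <- resolveVar("adt_CD34", cat)
  expect_identical(rv@modality, "adt")

  rv <- resolveVar("UMAP_2", cat)
  expect_identical(rv@kind, "reduction_dim")
  expect_identical(rv@reduction, "umap")
  expect_identical(rv@dimIndex, 2L)

  rv <- resolveVar("HLA_DRA", cat)        # underscore-containing feature
  expect_identical(rv@kind, "feature")
  expect_identical(rv@featureName, "HLA_DRA")

  rv <- resolveVar("adt_HLA_DR", cat)     # key + underscore feature
  expect_identical(rv@modality, "adt")
  expect_identical(rv@featureName, "HLA_DR")
})

test_that("out-of-range dims and ambiguous bare features are rejected", {
  cat <- grammarCatalog()
  r <- resolveVar("UMAP_3", cat)
  expect_false(is(r, "ResolvedVar"))
  expect_match(r$reason, "dim out of range")

  r <- resolveVar("CD117", cat)           # only in non-default adt
  expect_match(r$reason, "ambiguous without modality key")

  r <- resolveVar("bogus", cat)
  expect_match(r$reason, "not found")
})

test_that("bare features resolve without a key in single-modality catalogs", {
  solo <- dataCatalog(modalities = "rna",
                      features = list(rna = c("CD34", "CD117")),
                      layers = list(rna = "counts"),
                      metadataColumns = "cell_type",
                      cellIds = c("c1", "c2"))
  rv <- resolveVar("CD117", solo)
  expect_identical(rv@kind, "feature")
  expect_identical(rv@modality, "rna")
})

test_that("feature vars carry the effective layer", {
  cat <- grammarCatalog()
  expect_identical(resolveVar("CD34", cat)@layer, "data")      # default
  expect_identical(resolveVar("CD34", cat, layer = "counts")@layer, "counts")
  expect_identical(resolveVar("adt_CD117", cat)@layer, "data")
})

test_that("batch resolution dedups, preserves order, and reports drops", {
  cat <- grammarCatalog()
  rep <- resolveVars(c("cell_type", "CD34", "UMAP_1"), cat)
  expect_length(rep@resolved, 3L)
  expect_identical(nrow(rep@dropped), 0L)
  expect_identical(vapply(rep@resolved, function(r) r@requested, character(1)),
                   c("cell_type", "CD34", "UMAP_1"))

  rep <- resolveVars(c("CD34", "CD34"), cat)
  expect_length(rep@resolved, 1L)
  expect_identical(rep@deduplicated, "CD34")

  rep <- resolveVars(c("cell_type", "bogus"), cat)
  expect_length(rep@resolved, 1L)
  expect_identical(rep@dropped$requested, "bogus")

  expect_error(resolveVars(c("nope1", "nope2"), cat), "nope1.*nope2")
})

test_that("resolution is deterministic and matches an independent classifier", {
  cat <- grammarCatalog()
  vars <- c("cell_type", "CD34", "adt_CD34", "UMAP_1", "umap_2", "HLA_DRA",
            "rna_UMAP_1", "tsne_1", "PCA_10", "bogus")
  r1 <- resolveVars(vars, cat)
  r2 <- resolveVars(vars, cat)
  expect_identical(r1, r2)
  set.seed(99)
  for (i in 1:300) {
    case <- randomGrammarCase()
    got <- resolveVar(case$var, case$catalog)
    want <- bruteClassify(case$var, case$catalog)
    if (want$kind == "dropped") {
      expect_false(is(got, "ResolvedVar"),
                   label = sprintf("var '%s' should drop", case$var))
    } else {
      expect_s4_class(got, "ResolvedVar")
      expect_identical(got@kind, want$kind, label = case$var)
    }
  }
})
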
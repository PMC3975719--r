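test_that("term references normalise, render and reject as specified", {
  expect_identical(termRef(" icd:D69.6 "), "icd:D69.6")
  expect_identical(termRef("pnc-cc:deficiency-bone-marrow"),
                   "cc:deficiency-bone-marrow")
  expect_identical(termRef(termRef("cc:deficiency-bone-marrow")),
                   "cc:deficiency-bone-marrow")  # parse-then-render identity
  expect_identical(termNamespace("atc:B01AC04"), "atc")
  expect_identical(termLocal("icd:D50-D89"), "D50-D89")
  expect_error(termRef("foo:bar"), "invalid term reference")
  expect_error(termRef("icd:"), "invalid term reference")
  expect_error(termRef("icd:a b"), "invalid term reference")
})

test_that("terminology TSV loads into a graph whose broader chain is walkable", {
  fx <- bundledFixture("d696_enrichment")
  g <- readTerminology(fx$terminology)
  expect_s4_class(g, "ConceptGraph")
  expect_setequal(ancestors("icd:D69.6", g),
                  c("icd:D69", "icd:D65-D69", "icd:D50-D89"))
  expect_identical(concepts(g)$label[concepts(g)$ref == "icd:D69.6"],
                   "Thrombocytopenia, unspecified")
})

test_that("a single root row yields a one-concept graph with no edges", {
  f <- tmpText(c("scheme\tcode\tlabel\tparent_code\tequivalents",
                 "icd\tA00\tCholera\t\t"), ".tsv")
  g <- readTerminology(f)
  expect_equal(nrow(concepts(g)), 1L)
  expect_equal(nrow(broaderEdges(g)), 0L)
  expect_identical(ancestors("icd:A00", g), character(0))
})

test_that("loader rejects duplicates, missing parents and hierarchy cycles", {
  hdr <- "scheme\tcode\tlabel\tparent_code\tequivalents"
  expect_error(
    readTerminology(tmpText(c(hdr, "icd\tA00\tx\t\t", "icd\tA00\ty\t\t"))),
    "duplicate code.*A00")
  expect_error(
    readTerminology(tmpText(c(hdr, "icd\tA00\tx\tZ99\t"))),
    "missing code.*Z99")
  err <- tryCatch(
    readTerminology(tmpText(c(hdr, "icd\tA\ta\tB\t", "icd\tB\tb\tC\t",
                              "icd\tC\tc\tA\t"))),
    error = conditionMessage)
  expect_match(err, "cycle")
  expect_match(err, "icd:A.*icd:B.*icd:C|icd:B.*icd:C.*icd:A|icd:C.*icd:A.*icd:B")
})

test_that("ancestor sets on a random generated tree equal the parent-walk oracle", {
  g <- genTerminology(fixtureSpec(seed = 11L, nConceptsPerScheme = 100L,
                                  maxDepth = 5L))
  br <- broaderEdges(g)
  for (ref in sample(concepts(g)$ref, 60L)) {
    expect_identical(ancestors(ref, g), oracleAncestors(ref, br), label = ref)
  }
})

test_that("the printed collection definitions load with their exact shape", {
  fx <- bundledFixture("cardiac_collections")
  g <- readCollections(fx$collections, readTerminology(fx$terminology))
  expect_length(collections(g), 3L)
  crb <- collections(g)[["cc:cardiac-rhythm-abnormalities"]]
  expect_length(crb, 5L)
  expect_equal(sum(termNamespace(crb) == "cc"), 2L)
  expect_identical(crb, c("cc:bradycardia", "icd:R00", "cc:tachycardia",
                          "icd:O68.0", "icd:O68.2"))
})

test_that("the nested cardiac collection resolves to the seven-code union", {
  fx <- bundledFixture("cardiac_collections")
  g <- readCollections(fx$collections, readTerminology(fx$terminology))
  expect_identical(
    resolveCollection("cc:cardiac-rhythm-abnormalities", g),
    c("icd:I47", "icd:I49.5", "icd:O68.0", "icd:O68.2",
      "icd:R00", "icd:R00.0", "icd:R00.1"))
  ## a flat collection resolves to its own member set
  expect_identical(resolveCollection("cc:bradycardia", g),
                   sort(c("icd:I49.5", "icd:R00.1", "icd:O68.0")))
})

test_that("collection parsing flags malformed lines, redefinitions and cycles", {
  hdr <- "scheme\tcode\tlabel\tparent_code\tequivalents"
  g <- readTerminology(tmpText(c(hdr, "icd\tA00\tCholera\t\t")))
  g1 <- readCollections(tmpText("x = icd:A00"), g)
  expect_identical(collections(g1)[["cc:x"]], "icd:A00")
  expect_identical(resolveCollection("cc:x", g1), "icd:A00")

  expect_error(readCollections(tmpText("just some text"), g), "line 1")
  expect_error(readCollections(tmpText(c("x = icd:A00", "x = icd:A00")), g),
               "line 2.*redefinition")
  expect_warning(readCollections(tmpText("y = icd:A00 | icd:A00"), g),
                 "duplicate member")

  gc <- readCollections(tmpText(c("a = cc:b", "b = cc:a")), g)
  expect_error(resolveCollection("cc:a", gc), "cycle.*cc:a.*cc:b|cycle.*cc:b.*cc:a")
  gm <- readCollections(tmpText("a = cc:missing"), g)
  expect_error(resolveCollection("cc:a", gm), "missing collection")
})

test_that("resolution is idempotent, order-independent and matches the recursive oracle", {
  base <- genTerminology(fixtureSpec(seed = 21L, nConceptsPerScheme = 40L))
  set.seed(77)
  for (i in 1:30) {
    g <- randCollectionSystem(base, nColl = sample(3:8, 1L))
    for (nm in names(collections(g))) {
      got <- resolveCollection(nm, g)
      expect_identical(got, oracleResolveColl(nm, collections(g)), label = nm)
      ## shuffling member order never changes the resolved set
      g2 <- g
      g2@collections[[nm]] <- sample(collections(g)[[nm]])
      expect_identical(resolveCollection(nm, g2), got)
    }
  }
})

test_that("terminology TSV round-trips through writeTerminology", {
  fx <- bundledFixture("use_case_patient")
  g <- readTerminology(fx$terminology)
  f <- tempfile(fileext = ".tsv")
  writeTerminology(g, f)
  expectGraphsEqual(g, readTerminology(f))
})
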
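caseReportStub <- function(matched, administered, dd = 0L, recommended = 10L) {
  structure(list(dd_interactions = dd, dd_contraindications = 0L,
                 dx_interactions = 0L, dx_contraindications = 0L,
                 matched = matched, recommended = recommended,
                 administered = administered),
            class = "caseReport")
}

test_that("clinical cases validate history/diagnosis disjointness and prescriptions", {
  p <- patient("c1", c("icd:I10", "atc:A10BA02"), "elder", "male")
  cs <- clinicalCase(p, "icd:N11.0", "sub:ciprofloxacin")
  expect_s3_class(cs, "clinicalCase")
  expect_error(clinicalCase(p, "icd:I10", "sub:x"), "already in history")
  expect_error(clinicalCase(p, "icd:N11.0", character(0)), "non-empty")
})

test_that("a case firing no contraindication rules reports four zero counts", {
  fx <- bundledFixture("lisuride")
  g <- readTerminology(fx$terminology)
  rb <- readRuleBase(fx$rules)
  cs <- clinicalCase(patient("c", "icd:N97", "adult", "female"),
                     "icd:E22.1", "sub:lisuride")
  rep <- analyzeCase(cs, rb, g)
  expect_equal(rep$dd_interactions, 0L)
  expect_equal(rep$dd_contraindications, 0L)
  expect_equal(rep$dx_interactions, 0L)
  expect_equal(rep$dx_contraindications, 0L)
  ## lisuride fires on E22.1 & N97 and was prescribed
  expect_equal(rep$matched, 1L)
  expect_equal(rep$recommended, 1L)
})

test_that("an engineered drug-drug contraindication on a prescribed substance counts once", {
  hdr <- "scheme\tcode\tlabel\tparent_code\tequivalents"
  g <- readTerminology(tmpText(c(
    hdr,
    "icd\tN39.0\tUrinary tract infection\t\t",
    "atc\tB01AA03\tWarfarin\t\t",
    "sub\twarfarin\tWarfarin\t\tatc:B01AA03",
    "sub\taspirin\tAspirin\t\t",
    "sub\tnitrofurantoin\tNitrofurantoin\t\t"), ".tsv"))
  rb <- readRuleBase(tmpText(c(
    "nitrofurantoin = icd:N39.0",
    "aspirin = icd:N39.0",
    "!aspirin = atc:B01AA03",      # drug-drug: premise is a drug code
    "!nitrofurantoin = icd:N39.0 & icd:N39.0")))  # drug-disease premise
  cs <- clinicalCase(patient("c", "atc:B01AA03", "adult", "male"),
                     "icd:N39.0", c("sub:aspirin", "sub:nitrofurantoin"))
  rep <- analyzeCase(cs, rb, g)
  expect_equal(rep$dd_interactions, 1L)
  expect_equal(rep$dd_contraindications, 1L)  # aspirin was prescribed
  expect_equal(rep$dx_interactions, 1L)
  expect_equal(rep$dx_contraindications, 1L)  # nitrofurantoin was prescribed
  ## both indicated substances are contraindicated away: nothing final
  expect_equal(rep$recommended, 0L)
  expect_equal(rep$matched, 0L)
  expect_lte(rep$matched, min(rep$recommended, rep$administered))
})

test_that("matching tolerates ATC-coded prescriptions via closeMatch", {
  fx <- bundledFixture("use_case_patient")
  g <- readCollections(fx$collections, readTerminology(fx$terminology))
  rb <- readRuleBase(fx$rules)
  cs <- readCases(fx$cases)[[1]]
  rep <- analyzeCase(cs, rb, g)
  ## ciprofloxacin recommended as sub:, prescribed as atc:J01MA02
  expect_equal(rep$matched, 1L)
  expect_equal(rep$administered, 1L)
  expect_equal(rep$dd_interactions, 1L)   # ibuprofen vs antithrombotics
  expect_equal(rep$dx_interactions, 1L)   # metformin vs pyelonephritis
  expect_equal(rep$dd_contraindications, 0L)  # neither was prescribed
})

test_that("cohort aggregation reproduces the 51-of-76 match percentage", {
  ## 19 cases at 3/4 matched/administered plus two remainder cases
  reports <- c(lapply(1:17, function(i) caseReportStub(3L, 4L)),
               list(caseReportStub(0L, 4L), caseReportStub(0L, 4L)))
  expect_equal(sum(vapply(reports, `[[`, numeric(1), "matched")), 51)
  expect_equal(sum(vapply(reports, `[[`, numeric(1), "administered")), 76)
  cohort <- aggregateCases(reports)
  expect_equal(cohort$total_matched, 51)
  expect_equal(cohort$total_administered, 76)
  expect_equal(cohort$match_percentage, 67.1)
  ## one fully matched case reports 100.0
  expect_equal(aggregateCases(list(caseReportStub(5L, 5L)))$match_percentage,
               100.0)
  expect_error(aggregateCases(list()), "at least one")
  expect_error(aggregateCases(list(caseReportStub(1L, 1L)),
                              administeredTotal = 0), "positive")
})

test_that("cohort means match an independent recomputation with half-up rounding", {
  set.seed(404)
  reports <- lapply(1:15, function(i)
    structure(list(dd_interactions = sample(0:6, 1), dd_contraindications = sample(0:2, 1),
                   dx_interactions = sample(0:8, 1), dx_contraindications = sample(0:2, 1),
                   matched = sample(0:5, 1), recommended = sample(5:80, 1),
                   administered = sample(1:8, 1)),
              class = "caseReport"))
  cohort <- aggregateCases(reports)
  col <- function(f) vapply(reports, `[[`, numeric(1), f)
  hu2 <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100  # independent half-up
  expect_equal(cohort$mean_dd_interactions, hu2(sum(col("dd_interactions")) / 15))
  expect_equal(cohort$mean_dx_interactions, hu2(sum(col("dx_interactions")) / 15))
  expect_equal(cohort$avg_recommendations_per_case, hu2(sum(col("recommended")) / 15))
  expect_equal(cohort$match_percentage,
               floor(1000 * sum(col("matched")) / sum(col("administered")) +
                       0.5 + 1e-9) / 10)
  ## permutation invariance
  cohort2 <- aggregateCases(rev(reports))
  expect_identical(unclass(cohort), unclass(cohort2))
  ## explicit half-up tie: mean 0.125 over 2 decimals rounds to 0.13
  tie <- list(caseReportStub(1L, 1L, dd = 0L), caseReportStub(1L, 1L, dd = 0L),
              caseReportStub(1L, 1L, dd = 0L), caseReportStub(1L, 1L, dd = 1L))
  tie[[4]]$dd_interactions <- 0.5  # fractional to force the .005 tie
  expect_equal(aggregateCases(tie)$mean_dd_interactions, 0.13)
})

test_that("cohort reports serialize to JSON with all documented fields", {
  cohort <- aggregateCases(list(caseReportStub(2L, 3L)))
  txt <- writeCohortReport(cohort, tempfile(fileext = ".json"))
  parsed <- jsonlite::fromJSON(txt)
  expect_setequal(names(parsed),
                  c("n_cases", "mean_dd_interactions", "mean_dd_contraindications",
                    "mean_dx_interactions", "mean_dx_contraindications",
                    "total_administered", "total_matched",
                    "avg_recommendations_per_case", "match_percentage"))
})
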
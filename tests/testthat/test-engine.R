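useCaseSetup <- function() {
  fx <- bundledFixture("use_case_patient")
  g <- readCollections(fx$collections, readTerminology(fx$terminology))
  list(g = g, rb = readRuleBase(fx$rules), p = readPatient(fx$patient))
}

test_that("phase-1 selection filters rules by patient demographics", {
  lis <- parseRule("lisuride = icd:E22.0, ageGroup=adult or elder", "R0001")
  anyR <- parseRule("x = icd:A00", "R0002")
  rb <- ruleBase(list(lis, anyR))
  expect_identical(selectPhase1(rb, patient("a", "icd:A00", "adult")),
                   c(TRUE, TRUE))
  expect_identical(selectPhase1(rb, patient("c", "icd:A00", "child")),
                   c(FALSE, TRUE))  # {any} rules are always selected
  expect_identical(selectPhase1(rb, patient("e", "icd:A00", "elder", "female")),
                   c(TRUE, TRUE))
})

test_that("phase-2 keeps conjuncts sharing at least one term, firing needs all", {
  fx <- bundledFixture("lisuride")
  g <- readTerminology(fx$terminology)
  rb <- readRuleBase(fx$rules)
  conj <- expandRuleBase(rb)
  ## patient holding N97 only: the {E22.1, N97} conjunct is selected...
  ep <- enrichPatient(patient("p", "icd:N97", "adult"), g)
  sel <- selectPhase2(conj, ep)
  expect_identical(sel, c(FALSE, FALSE, TRUE))
  ## ...but fails full-premise firing
  expect_equal(nrow(fireRules(conj[sel, , drop = FALSE], ep)), 0L)
  ## a patient with the first disjunct's single premise fires it
  ep2 <- enrichPatient(patient("p2", "icd:E22.0", "adult"), g)
  fired <- fireRules(conj, ep2)
  expect_equal(nrow(fired), 1L)
  expect_identical(fired$substance, "sub:lisuride")
  expect_identical(fired$matched_premises[[1]], "icd:E22.0")
  ## demographics are re-checked at firing time
  epChild <- enrichPatient(patient("p3", "icd:E22.0", "child"), g)
  expect_equal(nrow(fireRules(conj, epChild)), 0L)
})

test_that("the use-case scenario recommends identically under both strategies", {
  s <- useCaseSetup()
  rs1 <- recommend(s$p, s$rb, s$g, strategy = "expanded")
  rs2 <- recommend(s$p, s$rb, s$g, strategy = "direct")
  expect_identical(recTriple(rs1), recTriple(rs2))
  ## the NSAID is indicated for the new diagnosis but excluded by the
  ## interaction with the antithrombotic the patient takes
  expect_true("sub:ibuprofen" %in% canTake(rs1))
  expect_true("sub:ibuprofen" %in% cannotTake(rs1))
  expect_false("sub:ibuprofen" %in% finalRecommendations(rs1))
  expect_setequal(finalRecommendations(rs1),
                  c("sub:ciprofloxacin", "sub:fosfomycin"))
  ## trace funnel is consistent
  tr <- selectionTrace(rs1)
  expect_lte(tr$final_set_size, tr$candidate_set_size)
  expect_lte(tr$candidate_set_size, tr$total_rules)
})

test_that("an empty rule base yields empty recommendation sets", {
  s <- useCaseSetup()
  rs <- recommend(s$p, ruleBase(list()), s$g)
  expect_identical(canTake(rs), character(0))
  expect_identical(cannotTake(rs), character(0))
  expect_identical(finalRecommendations(rs), character(0))
})

test_that("contraindication precedence always filters the final list", {
  s <- useCaseSetup()
  for (strat in c("expanded", "direct")) {
    rs <- recommend(s$p, s$rb, s$g, strategy = strat)
    expect_identical(finalRecommendations(rs),
                     setdiff(canTake(rs), cannotTake(rs)))
    expect_length(intersect(finalRecommendations(rs), cannotTake(rs)), 0L)
  }
})

test_that("identical inputs give byte-identical serialized recommendations", {
  s <- useCaseSetup()
  f1 <- tempfile(); f2 <- tempfile()
  writeRecommendation(recommend(s$p, s$rb, s$g), f1)
  s2 <- useCaseSetup()  # fully re-loaded from disk
  writeRecommendation(recommend(s2$p, s2$rb, s2$g), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("two-phase selection never changes recommendations (random grid)", {
  spec <- fixtureSpec(seed = 61L, nConceptsPerScheme = 40L, nCollections = 6L,
                      nRules = 120L, nPatients = 25L)
  g <- genCollections(spec, genTerminology(spec))
  rb <- genRulebase(spec, g)
  conj <- expandRuleBase(rb)
  for (p in genPatients(spec, g)) {
    ep <- enrichPatient(p, g)
    withSel <- recommend(ep, rb, g, conjuncts = conj)
    noSel <- recommend(ep, rb, g, conjuncts = conj, useSelection = FALSE)
    direct <- recommend(ep, rb, g, strategy = "direct")
    expect_identical(recTriple(withSel), recTriple(noSel), label = p@id)
    expect_identical(recTriple(withSel), recTriple(direct), label = p@id)
    expect_true(all(withSel@trace$final_set_size <=
                      withSel@trace$candidate_set_size))
  }
})

test_that("queryRecommendations filters by polarity and substance glob", {
  s <- useCaseSetup()
  rs <- recommend(s$p, s$rb, s$g)
  all <- queryRecommendations(rs)
  expect_identical(all$substance, sort(all$substance))
  contra <- queryRecommendations(rs, polarity = "contraindication")
  expect_setequal(contra$substance, cannotTake(rs))
  cipro <- queryRecommendations(rs, pattern = "cipro*")
  expect_identical(cipro$substance, "sub:ciprofloxacin")
  expect_true(all(nzchar(all$rule_ids)))
  expect_error(queryRecommendations(rs, polarity = "bogus"), "polarity")
  expect_error(queryRecommendations(rs, pattern = ""), "pattern")
})

test_that("recommendation Turtle export lists canTake and cannotTake triples", {
  s <- useCaseSetup()
  rs <- recommend(s$p, s$rb, s$g)
  txt <- writeRecommendationTTL(rs, s$p@id, tempfile(fileext = ".ttl"))
  expect_match(txt, "rxr:canTake")
  expect_match(txt, "rxr:cannotTake")
  expect_match(txt, "sub:ciprofloxacin")
})
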
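lisurideLine <- paste0("lisuride = icd:E22.0 | (icd:E22.1 & ",
                       "(icd:N91.0 | icd:N97)), ageGroup=adult or elder")

test_that("the lisuride indication parses to the expected AST and demographics", {
  r <- parseRule(lisurideLine)
  expect_identical(r@substance, "sub:lisuride")
  expect_identical(r@polarity, "indication")
  expect_setequal(r@ageGroups, c("adult", "elder"))
  expect_identical(r@sexGroups, "any")
  expect_identical(r@expr, list(
    kind = "or",
    children = list(
      list(kind = "atom", ref = "icd:E22.0"),
      list(kind = "and", children = list(
        list(kind = "atom", ref = "icd:E22.1"),
        list(kind = "or", children = list(
          list(kind = "atom", ref = "icd:N91.0"),
          list(kind = "atom", ref = "icd:N97"))))))))
})

test_that("& binds tighter than | and parentheses override", {
  r <- parseRule("a = icd:A & icd:B | icd:C")
  full <- parseRule("a = (icd:A & icd:B) | icd:C")  # fully parenthesized form
  expect_identical(r@expr, full@expr)
  expect_identical(r@expr$kind, "or")
  expect_identical(r@expr$children[[1]]$kind, "and")
  r2 <- parseRule("a = icd:A & (icd:B | icd:C)")
  expect_identical(r2@expr$kind, "and")
})

test_that("minimal rules default to any demographics; ! marks contraindication", {
  r <- parseRule("x = icd:A00")
  expect_identical(r@expr, list(kind = "atom", ref = "icd:A00"))
  expect_identical(r@ageGroups, "any")
  expect_identical(r@sexGroups, "any")
  expect_identical(r@polarity, "indication")
  rc <- parseRule("!x = atc:B01AC04")
  expect_identical(rc@polarity, "contraindication")
  expect_identical(rc@substance, "sub:x")
})

test_that("parse errors carry a column position and a reason", {
  expect_error(parseRule("x = (icd:A & icd:B"), "column.*unbalanced")
  expect_error(parseRule("x = icd:A | "), "column.*end of expression")
  expect_error(parseRule("x = foo:A"), "column 5")
  expect_error(parseRule("x = icd:A, ageGroup=adult, ageGroup=elder"),
               "duplicate ageGroup")
  expect_error(parseRule("x = icd:A, ageGroup=teen"), "unknown age group")
  expect_error(parseRule("x = icd:A icd:B"), "column.*unexpected")
  expect_error(parseRule("= icd:A"), "missing substance")
})

test_that("OR-elimination of the lisuride rule yields its three conjuncts", {
  conj <- expandRule(parseRule(lisurideLine))
  expect_equal(nrow(conj), 3L)
  expect_identical(conj$premises[[1]], "icd:E22.0")
  expect_identical(conj$premises[[2]], c("icd:E22.1", "icd:N91.0"))
  expect_identical(conj$premises[[3]], c("icd:E22.1", "icd:N97"))
  expect_true(all(vapply(conj$age_groups, setequal, logical(1),
                         c("adult", "elder"))))
})

test_that("pure-OR expands to k conjuncts, pure-AND to one, duplicates merge", {
  orRule <- parseRule("x = icd:A | icd:B | icd:C | icd:D")
  expect_equal(nrow(expandRule(orRule)), 4L)
  andRule <- parseRule("x = icd:A & icd:B & icd:C")
  andConj <- expandRule(andRule)
  expect_equal(nrow(andConj), 1L)
  expect_identical(andConj$premises[[1]], c("icd:A", "icd:B", "icd:C"))
  expect_equal(nrow(expandRule(parseRule("x = icd:A"))), 1L)
  ## identical disjuncts merge; repeated premises dedupe within a conjunct
  dup <- parseRule("x = (icd:A & icd:A) | icd:A")
  expect_equal(nrow(expandRule(dup)), 1L)
})

test_that("the expansion cap aborts combinatorial blow-ups by rule id", {
  wide <- paste(rep("(icd:A | icd:B)", 15L), collapse = " & ")
  r <- parseRule(paste("x =", wide), ruleId = "RBIG")
  expect_error(expandRule(r, cap = 1000L), "RBIG.*exceeds 1000")
})

test_that("DNF expansion is logically equivalent to the original expression", {
  set.seed(1234)
  atoms <- sprintf("icd:T%02d", 1:6)
  for (i in 1:100) {
    expr <- randExpr(atoms, maxDepth = 4L)
    rule <- new("MedicalRule", ruleId = "R1", substance = "sub:x",
                polarity = "indication", expr = expr,
                ageGroups = "any", sexGroups = "any")
    conj <- expandRule(rule)$premises
    used <- exprAtoms(expr)
    k <- length(used)
    for (mask in 0:(2^k - 1)) {
      trueAtoms <- used[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L]
      expect_identical(evalAssign(expr, trueAtoms),
                       dnfSatisfied(conj, trueAtoms))
    }
  }
})

test_that("direct evaluation matches hand evaluation of the printed rule", {
  expr <- parseRule(lisurideLine)@expr
  expect_true(evaluateExpr(expr, c("icd:E22.1", "icd:N97")))
  expect_false(evaluateExpr(expr, "icd:E22.1"))
  expect_true(evaluateExpr(expr, "icd:E22.0"))
  ## any expression holds when all of its atoms do (positive monotone logic)
  expect_true(evaluateExpr(expr, exprAtoms(expr)))
})

test_that("rendered rules re-parse to an identical AST", {
  set.seed(55)
  atoms <- c(sprintf("icd:A%02d", 1:5), "cc:grp", "atc:X01")
  for (i in 1:60) {
    r <- new("MedicalRule", ruleId = "R1", substance = "sub:drug",
             polarity = sample(c("indication", "contraindication"), 1L),
             expr = randExpr(atoms, maxDepth = 4L),
             ageGroups = sample(c("any", "adult", "elder"), 1L),
             sexGroups = sample(c("any", "female"), 1L))
    r2 <- parseRule(writeRuleLine(r))
    expect_identical(r2@expr, r@expr)
    expect_identical(r2@polarity, r@polarity)
    expect_identical(r2@ageGroups, r@ageGroups)
  }
})

test_that("rule bases round-trip with ids and version; duplicates are rejected", {
  rb <- ruleBase(list(
    parseRule(lisurideLine, "R0001"),
    parseRule("!warfarin = atc:B01AC04 | sub:aspirin", "R0002")),
    version = "2024-test")
  f <- tempfile(fileext = ".txt")
  writeRuleBase(rb, f)
  rb2 <- readRuleBase(f)
  expect_identical(rb2@version, "2024-test")
  expect_identical(ruleIds(rb2), c("R0001", "R0002"))
  for (i in 1:2) {
    expect_identical(rules(rb2)[[i]]@expr, rules(rb)[[i]]@expr)
    expect_identical(rules(rb2)[[i]]@polarity, rules(rb)[[i]]@polarity)
  }
  expect_error(readRuleBase(tmpText(c("[R1] x = icd:A", "[R1] y = icd:B"))),
               "duplicate rule id")
  ## ids auto-assigned in file order when absent
  rb3 <- readRuleBase(tmpText(c("# comment", "x = icd:A", "", "y = icd:B")))
  expect_identical(ruleIds(rb3), c("R0001", "R0002"))
})
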
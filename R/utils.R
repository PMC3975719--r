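# internal helpers

## sorted set semantics for character vectors of TermRefs
termSet <- function(x) sort(unique(as.character(x)), method = "radix")

## round half away from zero at d decimals (printed-table convention;
## base round() is half-to-even). Small epsilon guards binary representation.
roundHalfUp <- function(x, d = 0) {
  p <- 10^d
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so generators never perturb global randomness
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## demographic match: a rule group-set matches a patient group iff the rule
## allows 'any', the patient is 'any', or the patient's group is listed
groupMatches <- function(ruleGroups, patientGroup) {
  "any" %in% ruleGroups || identical(patientGroup, "any") ||
    patientGroup %in% ruleGroups
}

## stop with a condition class the CLI maps to exit code 2
validationStop <- function(...) {
  stop(errorCondition(paste0(...), class = c("rxrValidationError", "error")))
}
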
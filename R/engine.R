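#' Phase-1 rule selection: demographic filter
#'
#' First iteration of the two-phase selection strategy: keep the rules whose
#' age-group and sex-group constraints are compatible with the patient (a
#' rule or patient group of `"any"` matches everything). The result is the
#' candidate subset conventionally written \eqn{\hat{A}}.
#'
#' Selection is a pure pre-filter: rule firing re-checks demographics, so
#' skipping selection never changes recommendations, only work.
#'
#' @param rb a [RuleBase-class] (or list of [MedicalRule-class]).
#' @param p a [Patient-class] (or [EnrichedPatient-class]).
#' @return logical vector, one element per rule: selected or not.
#' @export
selectPhase1 <- function(rb, p) {
  ruleList <- if (is(rb, "RuleBase")) rules(rb) else rb
  age <- ageGroup(p); sex <- sexGroup(p)
  vapply(ruleList, function(r)
    groupMatches(r@ageGroups, age) && groupMatches(r@sexGroups, sex),
    logical(1))
}

#' Phase-2 rule selection: premise-term overlap
#'
#' Second iteration, applied to the *expanded* conjunctive rules of the
#' demographic candidates: keep the conjuncts whose premise set contains at
#' least one of the enriched patient's terms. Because the patient record is
#' already closed under inference, this is plain string/set matching. The
#' result is the final selected subset \eqn{R \subseteq \hat{A}}; for
#' negation-free rules every rule that could fire shares at least one premise
#' term with the patient, so the filter is sound (it never changes the
#' recommendations).
#'
#' @param conjuncts a conjunctive-rule data.frame from [expandRuleBase()].
#' @param ep an [EnrichedPatient-class].
#' @return logical vector over the conjunct rows.
#' @export
selectPhase2 <- function(conjuncts, ep) {
  stopifnot(is(ep, "EnrichedPatient"))
  terms <- allTerms(ep)
  vapply(conjuncts$premises, function(pr) any(pr %in% terms), logical(1))
}

#' Fire conjunctive rules against an enriched patient
#'
#' A conjunct fires iff *all* its premises are held by the enriched patient
#' and its demographic constraints match. Output order is deterministic:
#' rule id, then conjunct index.
#'
#' @param conjuncts a conjunctive-rule data.frame (see [expandRuleBase()]).
#' @param ep an [EnrichedPatient-class].
#' @return data.frame of fired conjuncts with columns `rule_id`, `conjunct`,
#'   `substance`, `polarity` and list column `matched_premises`.
#' @export
fireRules <- function(conjuncts, ep) {
  stopifnot(is(ep, "EnrichedPatient"))
  terms <- allTerms(ep)
  age <- ageGroup(ep); sex <- sexGroup(ep)
  hit <- vapply(seq_len(nrow(conjuncts)), function(i)
    groupMatches(conjuncts$age_groups[[i]], age) &&
      groupMatches(conjuncts$sex_groups[[i]], sex) &&
      all(conjuncts$premises[[i]] %in% terms),
    logical(1))
  f <- conjuncts[hit, , drop = FALSE]
  f <- f[order(f$parent_id, f$conjunct, method = "radix"), , drop = FALSE]
  data.frame(rule_id = f$parent_id, conjunct = f$conjunct,
             substance = f$substance, polarity = f$polarity,
             matched_premises = I(unname(f$premises)),
             stringsAsFactors = FALSE)
}

emptyFired <- function() {
  data.frame(rule_id = character(), conjunct = integer(),
             substance = character(), polarity = character(),
             matched_premises = I(list()), stringsAsFactors = FALSE)
}

#' Compute drug recommendations for a patient
#'
#' The full two-layer pipeline. The patient is first enriched against the
#' terminology graph ([enrichPatient()]); the rule base is then evaluated by
#' one of two interchangeable strategies:
#'
#' * `"expanded"` -- demographic selection ([selectPhase1()]), OR-elimination
#'   into conjunctive rules ([expandRuleBase()]), premise-overlap selection
#'   ([selectPhase2()]), then firing ([fireRules()]). This is the route a
#'   disjunction-free rule engine must take.
#' * `"direct"` -- demographic selection, then direct boolean evaluation of
#'   each un-expanded rule ([evaluateExpr()]), as a rule engine whose language
#'   allows OR in the body would do. No premise pre-selection is needed.
#'
#' Both strategies provably return identical `canTake`/`cannotTake`/`final`
#' sets. Fired indication rules contribute their substance to `canTake`,
#' fired contraindications to `cannotTake`, and the final recommendation list
#' applies contraindication precedence: `final = canTake \ cannotTake` (the
#' presence of any interaction, however minor, excludes the substance --
#' interactions are binary, with no severity weighting). All output sets are
#' sorted lexicographically for reproducibility.
#'
#' @param p a [Patient-class] (or an already-enriched
#'   [EnrichedPatient-class], in which case `graph` is only used for
#'   consistency checks).
#' @param rb a [RuleBase-class].
#' @param graph a [ConceptGraph-class].
#' @param strategy `"expanded"` or `"direct"`.
#' @param useSelection logical; disable to run without the phase-1/phase-2
#'   pre-filters (same results, more work -- useful for verifying selection
#'   soundness).
#' @param cap expansion cap per rule, as in [expandRule()].
#' @param conjuncts optional precomputed [expandRuleBase()] output for `rb`;
#'   pass it when scoring many patients against one rule base to avoid
#'   re-expanding per call.
#' @return a [RecommendationSet-class].
#' @examples
#' fx <- bundledFixture("lisuride")
#' g <- readTerminology(fx$terminology)
#' rb <- readRuleBase(fx$rules)
#' p <- readPatient(fx$patient)
#' recommend(p, rb, g)
#' @export
recommend <- function(p, rb, graph,
                      strategy = c("expanded", "direct"),
                      useSelection = TRUE, cap = 10000L, conjuncts = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(is(rb, "RuleBase"), is(graph, "ConceptGraph"))
  ep <- if (is(p, "EnrichedPatient")) p else enrichPatient(p, graph)
  ruleList <- rules(rb)
  phase1 <- if (useSelection) selectPhase1(rb, ep) else
    rep(TRUE, length(ruleList))

  if (strategy == "expanded") {
    allConj <- if (is.null(conjuncts)) expandRuleBase(rb, cap) else conjuncts
    total <- if (is.null(allConj)) 0L else nrow(allConj)
    keepIds <- vapply(ruleList[phase1], function(r) r@ruleId, character(1))
    conj <- if (total) allConj[allConj$parent_id %in% keepIds, , drop = FALSE]
            else NULL
    if (!NROW(conj)) {
      fired <- emptyFired()
      candN <- 0L; finalN <- 0L; selIds <- character(0)
    } else {
      phase2 <- if (useSelection) selectPhase2(conj, ep) else
        rep(TRUE, nrow(conj))
      sel <- conj[phase2, , drop = FALSE]
      fired <- fireRules(sel, ep)
      candN <- nrow(conj); finalN <- nrow(sel)
      selIds <- unique(sel$parent_id)
    }
    trace <- list(total_rules = total, candidate_set_size = candN,
                  final_set_size = finalN, selected_ids = selIds,
                  strategy = "expanded")
  } else {
    terms <- allTerms(ep)
    cand <- ruleList[phase1]
    hit <- vapply(cand, function(r) evaluateExpr(r@expr, terms), logical(1))
    firedRulesL <- cand[hit]
    fired <- if (length(firedRulesL)) {
      data.frame(
        rule_id = vapply(firedRulesL, function(r) r@ruleId, character(1)),
        conjunct = rep(NA_integer_, length(firedRulesL)),
        substance = vapply(firedRulesL, function(r) r@substance, character(1)),
        polarity = vapply(firedRulesL, function(r) r@polarity, character(1)),
        matched_premises = I(lapply(firedRulesL, function(r)
          intersect(exprAtoms(r@expr), terms))),
        stringsAsFactors = FALSE)
    } else emptyFired()
    fired <- fired[order(fired$rule_id, method = "radix"), , drop = FALSE]
    trace <- list(total_rules = length(ruleList),
                  candidate_set_size = length(cand),
                  final_set_size = length(cand),
                  selected_ids = vapply(cand, function(r) r@ruleId, character(1)),
                  strategy = "direct")
  }
  rownames(fired) <- NULL
  can <- termSet(fired$substance[fired$polarity == "indication"])
  cannot <- termSet(fired$substance[fired$polarity == "contraindication"])
  rs <- new("RecommendationSet", canTake = can, cannotTake = cannot,
            final = setdiff(can, cannot), fired = fired, trace = trace)
  validObject(rs)
  rs
}

#' Query a RecommendationSet
#'
#' Flattens a recommendation set into stable, sorted records, optionally
#' filtered by polarity and/or a glob pattern on the substance name -- the
#' structured stand-in for querying the recommendation triples with SPARQL.
#'
#' @param rs a [RecommendationSet-class].
#' @param polarity optional, `"indication"` (canTake side) or
#'   `"contraindication"` (cannotTake side).
#' @param pattern optional substance-name glob (e.g. `"lis*"`), matched
#'   against the bare substance name.
#' @return data.frame with columns `substance`, `polarity`, `in_final`,
#'   `rule_ids` (comma-separated witnesses), sorted by substance then
#'   polarity.
#' @export
queryRecommendations <- function(rs, polarity = NULL, pattern = NULL) {
  stopifnot(is(rs, "RecommendationSet"))
  if (!is.null(polarity) &&
      !polarity %in% c("indication", "contraindication"))
    validationStop("polarity filter must be 'indication' or 'contraindication'")
  if (!is.null(pattern) &&
      (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)))
    validationStop("pattern must be a single non-empty glob string")
  f <- firedRules(rs)
  rows <- unique(data.frame(substance = f$substance, polarity = f$polarity,
                            stringsAsFactors = FALSE))
  if (nrow(rows)) {
    rows$in_final <- rows$substance %in% finalRecommendations(rs) &
      rows$polarity == "indication"
    rows$rule_ids <- vapply(seq_len(nrow(rows)), function(i)
      paste(sort(unique(f$rule_id[f$substance == rows$substance[i] &
                                    f$polarity == rows$polarity[i]])),
            collapse = ","), character(1))
  } else {
    rows$in_final <- logical(0)
    rows$rule_ids <- character(0)
  }
  if (!is.null(polarity)) rows <- rows[rows$polarity == polarity, , drop = FALSE]
  if (!is.null(pattern))
    rows <- rows[grepl(utils::glob2rx(pattern), termLocal(rows$substance)), ,
                 drop = FALSE]
  rows <- rows[order(rows$substance, rows$polarity, method = "radix"), ,
               drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Serialize a RecommendationSet
#'
#' `writeRecommendation()` emits the documented JSON schema (sorted sets,
#' fired-rule provenance, selection trace); `writeRecommendationTTL()` exports
#' the recommendation triples as Turtle using the framework properties
#' `rxr:canTake` / `rxr:cannotTake`, so any external SPARQL engine can consume
#' them.
#'
#' @param rs a [RecommendationSet-class].
#' @param file output path ("" for stdout in the JSON case).
#' @param patientId subject id for the Turtle export.
#' @return the serialized text, invisibly.
#' @export
writeRecommendation <- function(rs, file = "") {
  stopifnot(is(rs, "RecommendationSet"))
  f <- firedRules(rs)
  obj <- list(
    can_take = canTake(rs),
    cannot_take = cannotTake(rs),
    final = finalRecommendations(rs),
    fired = lapply(seq_len(nrow(f)), function(i) list(
      rule_id = f$rule_id[i],
      conjunct = if (is.na(f$conjunct[i])) NULL else f$conjunct[i],
      substance = f$substance[i],
      polarity = f$polarity[i],
      matched_premises = f$matched_premises[[i]])),
    trace = selectionTrace(rs))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (nzchar(file)) writeLines(txt, file) else cat(txt, "\n")
  invisible(as.character(txt))
}

#' @rdname writeRecommendation
#' @export
writeRecommendationTTL <- function(rs, patientId, file = "") {
  stopifnot(is(rs, "RecommendationSet"))
  lines <- c(
    paste0("@prefix rxr: <", RXR_FRAMEWORK_IRI, "> ."),
    paste0("@prefix sub: <", RXR_NS_IRI("sub"), "> ."),
    "")
  subj <- paste0("rxr:patient-", patientId)
  stmt <- character(0)
  if (length(canTake(rs)))
    stmt <- c(stmt, paste0("    rxr:canTake ",
                           paste(ttlTerm(canTake(rs)), collapse = " , ")))
  if (length(cannotTake(rs)))
    stmt <- c(stmt, paste0("    rxr:cannotTake ",
                           paste(ttlTerm(cannotTake(rs)), collapse = " , ")))
  if (length(stmt)) {
    lines <- c(lines, paste0(subj, " a rxr:Patient ;"),
               paste0(stmt, c(rep(" ;", length(stmt) - 1L), " .")))
  } else {
    lines <- c(lines, paste0(subj, " a rxr:Patient ."))
  }
  if (nzchar(file)) writeLines(lines, file) else cat(lines, sep = "\n")
  invisible(paste(lines, collapse = "\n"))
}
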
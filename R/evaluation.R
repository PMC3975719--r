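#' Clinical cases for quality evaluation
#'
#' A clinical case pairs a patient's history (active diseases plus current
#' medication, as the patient's asserted record) with the newly diagnosed
#' condition(s) of the encounter and the medication that was actually
#' prescribed. Cases are the input to [analyzeCase()], which compares the
#' engine's recommendations against the real prescriptions.
#'
#' @param patient a [Patient-class] holding the history.
#' @param newDiagnoses TermRefs of the encounter's new diagnoses; must be
#'   disjoint from the history.
#' @param prescribed non-empty TermRefs of the substances/drugs actually
#'   given (substance `sub:` names or ATC codes).
#' @return a classed list (`clinicalCase`).
#' @export
clinicalCase <- function(patient, newDiagnoses, prescribed) {
  stopifnot(is(patient, "Patient"))
  newDiagnoses <- termSet(termRef(newDiagnoses))
  prescribed <- termSet(termRef(prescribed))
  overlap <- intersect(newDiagnoses, patientData(patient))
  if (length(overlap))
    validationStop("new diagnoses already in history: ",
                   paste(overlap, collapse = ", "))
  if (!length(prescribed))
    validationStop("prescribed set must be non-empty for match statistics")
  structure(list(patient = patient, new_diagnoses = newDiagnoses,
                 prescribed = prescribed),
            class = "clinicalCase")
}

#' Read evaluation cases from JSON
#'
#' Format: a JSON array of
#' `{"patient": {<patient record>}, "new_diagnoses": [...],
#' "prescribed": [...]}` objects, with the patient record as in
#' [readPatient()].
#'
#' @param file JSON path.
#' @return list of `clinicalCase` objects.
#' @export
readCases <- function(file) {
  x <- jsonlite::fromJSON(file, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  lapply(x, function(rec) {
    p <- rec$patient
    clinicalCase(
      patient(p$id, unlist(p$data), p$age_group %||% "any",
              p$sex_group %||% "any"),
      unlist(rec$new_diagnoses), unlist(rec$prescribed))
  })
}

## closeMatch-closed expansion of a term set (chains included)
equivalenceClose <- function(terms, graph) {
  idx <- closeMatchIndex(graph)
  out <- terms
  repeat {
    more <- setdiff(unique(unlist(idx[intersect(out, names(idx))],
                                  use.names = FALSE)), out)
    if (!length(more)) break
    out <- c(out, more)
  }
  termSet(out)
}

## drug vs disease classification of a premise term; cc collections count as
## drug only when every resolved member is a drug term
premiseClass <- function(refs, resolved) {
  vapply(refs, function(r) {
    ns <- termNamespace(r)
    if (ns %in% RXR_DRUG_NS) return("drug")
    if (ns %in% RXR_DISEASE_NS) return("disease")
    members <- resolved[[r]]
    if (!is.null(members) && length(members) &&
        all(termNamespace(members) %in% RXR_DRUG_NS)) "drug" else "disease"
  }, character(1))
}

#' Analyze one clinical case against the engine
#'
#' Runs [recommend()] for the case's full record (history plus new
#' diagnoses) and derives the per-case quality statistics:
#'
#' * `dd_interactions` -- fired contraindication rules all of whose matched
#'   premises are drug/substance terms (a drug--drug interaction exists for
#'   the patient, whether or not the flagged substance was given);
#' * `dd_contraindications` -- the subset of those whose substance is among
#'   the actually prescribed drugs (modulo closeMatch equivalence);
#' * `dx_interactions` / `dx_contraindications` -- the same two counts for
#'   fired contraindication rules with at least one disease-term premise
#'   matched (drug--disease interactions);
#' * `matched` -- how many prescribed drugs appear in the final
#'   recommendation list (again modulo closeMatch, since prescriptions are
#'   often ATC-coded while recommendations are substances);
#' * `recommended` -- the size of the final list;
#' * `administered` -- the number of prescribed drugs.
#'
#' Fired rules are counted once per original rule (conjuncts of one rule are
#' not double-counted); a rule's matched premises are pooled over its fired
#' conjuncts. The interaction-vs-contraindication split (fired rule vs fired
#' rule on a prescribed substance) is this package's operational definition
#' of the distinction; see the methods vignette.
#'
#' @param case a [clinicalCase()].
#' @param rb a [RuleBase-class].
#' @param graph a [ConceptGraph-class].
#' @param ... passed to [recommend()] (e.g. `strategy`, `conjuncts`).
#' @return a classed list (`caseReport`) with the counts above.
#' @export
analyzeCase <- function(case, rb, graph, ...) {
  stopifnot(inherits(case, "clinicalCase"))
  p0 <- case$patient
  full <- patient(p0@id, c(patientData(p0), case$new_diagnoses),
                  ageGroup(p0), sexGroup(p0))
  rs <- recommend(full, rb, graph, ...)
  f <- firedRules(rs)
  contra <- f[f$polarity == "contraindication", , drop = FALSE]
  resolved <- resolveAllCollections(graph)
  prescribedEq <- equivalenceClose(case$prescribed, graph)
  ddI <- ddC <- dxI <- dxC <- 0L
  for (rid in unique(contra$rule_id)) {
    rows <- contra[contra$rule_id == rid, , drop = FALSE]
    prem <- termSet(unlist(rows$matched_premises, use.names = FALSE))
    cls <- premiseClass(prem, resolved)
    substancePrescribed <-
      any(equivalenceClose(rows$substance[1], graph) %in% prescribedEq)
    if (length(cls) && all(cls == "drug")) {
      ddI <- ddI + 1L
      if (substancePrescribed) ddC <- ddC + 1L
    }
    if (any(cls == "disease")) {
      dxI <- dxI + 1L
      if (substancePrescribed) dxC <- dxC + 1L
    }
  }
  final <- finalRecommendations(rs)
  finalEq <- equivalenceClose(final, graph)
  matched <- sum(vapply(case$prescribed, function(d)
    any(equivalenceClose(d, graph) %in% finalEq), logical(1)))
  structure(list(dd_interactions = ddI, dd_contraindications = ddC,
                 dx_interactions = dxI, dx_contraindications = dxC,
                 matched = as.integer(matched),
                 recommended = length(final),
                 administered = length(case$prescribed)),
            class = "caseReport")
}

#' Aggregate per-case reports into a cohort report
#'
#' Arithmetic means of the four interaction/contraindication counts (rounded
#' half-up to 2 decimals), totals, and the headline match percentage
#' `100 * total_matched / total_administered`, rounded half-up to 1 decimal
#' -- e.g. 51 matching of 76 administered reports 67.1. Aggregation is
#' permutation-invariant over cases.
#'
#' @param reports list of `caseReport` objects from [analyzeCase()].
#' @param administeredTotal optional override for the administered-drug total
#'   (defaults to the sum over the reports).
#' @return a classed list (`cohortReport`) with fields `n_cases`, the four
#'   means, `total_administered`, `total_matched`,
#'   `avg_recommendations_per_case` and `match_percentage`.
#' @export
aggregateCases <- function(reports, administeredTotal = NULL) {
  if (!length(reports)) validationStop("need at least one case report")
  stopifnot(all(vapply(reports, inherits, logical(1), "caseReport")))
  g <- function(field) vapply(reports, function(r) as.numeric(r[[field]]),
                              numeric(1))
  administered <- administeredTotal %||% sum(g("administered"))
  if (administered <= 0)
    validationStop("administered total must be positive")
  matched <- sum(g("matched"))
  structure(list(
    n_cases = length(reports),
    mean_dd_interactions = roundHalfUp(mean(g("dd_interactions")), 2),
    mean_dd_contraindications = roundHalfUp(mean(g("dd_contraindications")), 2),
    mean_dx_interactions = roundHalfUp(mean(g("dx_interactions")), 2),
    mean_dx_contraindications = roundHalfUp(mean(g("dx_contraindications")), 2),
    total_administered = administered,
    total_matched = matched,
    avg_recommendations_per_case = roundHalfUp(mean(g("recommended")), 2),
    match_percentage = roundHalfUp(100 * matched / administered, 1)),
    class = "cohortReport")
}

#' @export
print.cohortReport <- function(x, ...) {
  cat("Cohort quality report over", x$n_cases, "case(s)\n")
  cat(sprintf("  %-38s %6.2f\n", "Drug-drug interactions/case",
              x$mean_dd_interactions))
  cat(sprintf("  %-38s %6.2f\n", "Drug-drug contraindications/case",
              x$mean_dd_contraindications))
  cat(sprintf("  %-38s %6.2f\n", "Drug-disease interactions/case",
              x$mean_dx_interactions))
  cat(sprintf("  %-38s %6.2f\n", "Drug-disease contraindications/case",
              x$mean_dx_contraindications))
  cat(sprintf("  %-38s %6d\n", "Total administered drugs",
              as.integer(x$total_administered)))
  cat(sprintf("  %-38s %6d\n", "Matching recommendations",
              as.integer(x$total_matched)))
  cat(sprintf("  %-38s %6.2f\n", "Av. recommendations/case",
              x$avg_recommendations_per_case))
  cat(sprintf("  %-38s %5.1f%%\n", "Percentage (matching/administered)",
              x$match_percentage))
  invisible(x)
}

#' @export
print.caseReport <- function(x, ...) {
  cat("Case report: dd", x$dd_interactions, "/", x$dd_contraindications,
      "(interactions/contraind.), dx", x$dx_interactions, "/",
      x$dx_contraindications, "; matched", x$matched, "of",
      x$administered, "administered,", x$recommended, "recommended\n")
  invisible(x)
}

#' Write a cohort report as JSON
#'
#' @param report a `cohortReport`.
#' @param file output path ("" for stdout).
#' @return the JSON text, invisibly.
#' @export
writeCohortReport <- function(report, file = "") {
  stopifnot(inherits(report, "cohortReport"))
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                          digits = NA)
  if (nzchar(file)) writeLines(txt, file) else cat(txt, "\n")
  invisible(as.character(txt))
}
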
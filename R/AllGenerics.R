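#' Accessors for the package's S4 containers
#'
#' Small read-only accessors; slots are never reached into directly by user
#' code.
#'
#' @param x a [ConceptGraph-class], [Patient-class], [EnrichedPatient-class],
#'   [RuleBase-class] or [RecommendationSet-class] object, as appropriate.
#' @return the corresponding component (see each method's description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("concepts", function(x) standardGeneric("concepts"))
#' @rdname accessors
#' @export
setGeneric("schemes", function(x) standardGeneric("schemes"))
#' @rdname accessors
#' @export
setGeneric("collections", function(x) standardGeneric("collections"))
#' @rdname accessors
#' @export
setGeneric("broaderEdges", function(x) standardGeneric("broaderEdges"))
#' @rdname accessors
#' @export
setGeneric("closeMatches", function(x) standardGeneric("closeMatches"))
#' @rdname accessors
#' @export
setGeneric("danglingRefs", function(x) standardGeneric("danglingRefs"))
#' @rdname accessors
#' @export
setGeneric("patientData", function(x) standardGeneric("patientData"))
#' @rdname accessors
#' @export
setGeneric("ageGroup", function(x) standardGeneric("ageGroup"))
#' @rdname accessors
#' @export
setGeneric("sexGroup", function(x) standardGeneric("sexGroup"))
#' @rdname accessors
#' @export
setGeneric("allTerms", function(x) standardGeneric("allTerms"))
#' @rdname accessors
#' @export
setGeneric("inferredTerms", function(x) standardGeneric("inferredTerms"))
#' @rdname accessors
#' @export
setGeneric("termProvenance", function(x) standardGeneric("termProvenance"))
#' @rdname accessors
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))
#' @rdname accessors
#' @export
setGeneric("ruleIds", function(x) standardGeneric("ruleIds"))
#' @rdname accessors
#' @export
setGeneric("canTake", function(x) standardGeneric("canTake"))
#' @rdname accessors
#' @export
setGeneric("cannotTake", function(x) standardGeneric("cannotTake"))
#' @rdname accessors
#' @export
setGeneric("finalRecommendations", function(x) standardGeneric("finalRecommendations"))
#' @rdname accessors
#' @export
setGeneric("firedRules", function(x) standardGeneric("firedRules"))
#' @rdname accessors
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))

#' @rdname accessors
setMethod("concepts", "ConceptGraph", function(x) x@concepts)
#' @rdname accessors
setMethod("schemes", "ConceptGraph", function(x) x@schemes)
#' @rdname accessors
setMethod("collections", "ConceptGraph", function(x) x@collections)
#' @rdname accessors
setMethod("broaderEdges", "ConceptGraph", function(x) x@broader)
#' @rdname accessors
setMethod("closeMatches", "ConceptGraph", function(x) x@closeMatch)
#' @rdname accessors
setMethod("danglingRefs", "ConceptGraph", function(x) x@dangling)

#' @rdname accessors
setMethod("patientData", "Patient", function(x) x@data)
#' @rdname accessors
setMethod("ageGroup", "Patient", function(x) x@ageGroup)
#' @rdname accessors
setMethod("sexGroup", "Patient", function(x) x@sexGroup)
#' @rdname accessors
setMethod("patientData", "EnrichedPatient", function(x) x@patient@data)
#' @rdname accessors
setMethod("ageGroup", "EnrichedPatient", function(x) x@patient@ageGroup)
#' @rdname accessors
setMethod("sexGroup", "EnrichedPatient", function(x) x@patient@sexGroup)
#' @rdname accessors
setMethod("inferredTerms", "EnrichedPatient", function(x) x@inferred)
#' @rdname accessors
setMethod("termProvenance", "EnrichedPatient", function(x) x@provenance)
#' @rdname accessors
setMethod("allTerms", "EnrichedPatient",
          function(x) termSet(c(x@patient@data, x@inferred)))

#' @rdname accessors
setMethod("rules", "RuleBase", function(x) x@rules)
#' @rdname accessors
setMethod("ruleIds", "RuleBase",
          function(x) vapply(x@rules, function(r) r@ruleId, character(1)))

#' @rdname accessors
setMethod("canTake", "RecommendationSet", function(x) x@canTake)
#' @rdname accessors
setMethod("cannotTake", "RecommendationSet", function(x) x@cannotTake)
#' @rdname accessors
setMethod("finalRecommendations", "RecommendationSet", function(x) x@final)
#' @rdname accessors
setMethod("firedRules", "RecommendationSet", function(x) x@fired)
#' @rdname accessors
setMethod("selectionTrace", "RecommendationSet", function(x) x@trace)

setMethod("show", "ConceptGraph", function(object) {
  cat("ConceptGraph with", nrow(object@concepts), "concepts in",
      nrow(object@schemes), "scheme(s),",
      nrow(object@broader), "broader edge(s),",
      nrow(object@closeMatch) / 2, "closeMatch pair(s),",
      length(object@collections), "collection(s)\n")
  if (length(object@dangling))
    cat("  dangling refs:", paste(object@dangling, collapse = ", "), "\n")
})

setMethod("show", "Patient", function(object) {
  cat("Patient", object@id, sprintf("(%s, %s)", object@ageGroup, object@sexGroup),
      "with", length(object@data), "asserted term(s)\n")
})

setMethod("show", "EnrichedPatient", function(object) {
  cat("EnrichedPatient", object@patient@id, "-",
      length(object@patient@data), "asserted +",
      length(object@inferred), "inferred term(s)\n")
})

setMethod("show", "MedicalRule", function(object) {
  cat(writeRuleLine(object), "\n")
})

setMethod("show", "RuleBase", function(object) {
  np <- sum(vapply(object@rules, function(r) r@polarity == "indication", logical(1)))
  cat("RuleBase (version", object@version, "):", length(object@rules),
      "rule(s) --", np, "indication(s),", length(object@rules) - np,
      "contraindication(s)\n")
})

setMethod("show", "RecommendationSet", function(object) {
  cat("RecommendationSet:", length(object@canTake), "canTake,",
      length(object@cannotTake), "cannotTake,",
      length(object@final), "final recommendation(s);",
      nrow(object@fired), "fired rule conjunct(s)\n")
  tr <- object@trace
  if (length(tr))
    cat(sprintf("  selection: %d total -> %d demographic candidates -> %d premise-matched (%s strategy)\n",
                tr$total_rules, tr$candidate_set_size, tr$final_set_size,
                tr$strategy %||% "expanded"))
})
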
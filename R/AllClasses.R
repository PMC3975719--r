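#' @import methods
NULL

#' ConceptGraph: a multi-scheme medical terminology graph
#'
#' The knowledge backbone of the package: every coded concept across all
#' terminology schemes (ICD-10, ATC, UNII, ICTV, substances, custom concepts)
#' together with the direct `broader` hierarchy edges, symmetric `closeMatch`
#' equivalences (e.g. substance \eqn{\equiv} ATC code) and named custom concept
#' collections (expert-defined unions of codes and/or other collections).
#'
#' Only *direct* broader edges are stored; transitive closure is computed at
#' inference time (see [ancestors()]), mirroring the split between stored SKOS
#' data and reasoner output.
#'
#' @slot concepts data.frame with columns `ref`, `scheme`, `label`; one row per
#'   concept, `ref` unique.
#' @slot broader data.frame with columns `ref`, `parent`: direct parent edges.
#'   The edge relation must be acyclic (the hierarchy is a DAG; multiple
#'   parents are allowed).
#' @slot closeMatch data.frame with columns `ref`, `match`; stored symmetrised
#'   (both directions present).
#' @slot collections named list; names are `cc:` refs, elements are ordered
#'   character vectors of member refs (codes and/or other collections).
#' @slot schemes data.frame with columns `id`, `title`.
#' @slot dangling character vector of refs that were referenced (as closeMatch
#'   targets) but are not defined concepts; flagged, not dropped.
#' @seealso [readTerminology()], [readCollections()], [resolveCollection()],
#'   [writeSKOS()], [readSKOS()]
#' @export
setClass("ConceptGraph",
  representation(
    concepts    = "data.frame",
    broader     = "data.frame",
    closeMatch  = "data.frame",
    collections = "list",
    schemes     = "data.frame",
    dangling    = "character"
  ),
  prototype(
    concepts    = data.frame(ref = character(), scheme = character(),
                             label = character(), stringsAsFactors = FALSE),
    broader     = data.frame(ref = character(), parent = character(),
                             stringsAsFactors = FALSE),
    closeMatch  = data.frame(ref = character(), match = character(),
                             stringsAsFactors = FALSE),
    collections = list(),
    schemes     = data.frame(id = character(), title = character(),
                             stringsAsFactors = FALSE),
    dangling    = character(0)
  )
)

setValidity("ConceptGraph", function(object) {
  msgs <- character(0)
  cn <- object@concepts
  if (!all(c("ref", "scheme", "label") %in% names(cn)))
    return("concepts must have columns ref, scheme, label")
  if (anyDuplicated(cn$ref))
    msgs <- c(msgs, paste0("duplicate concept ref(s): ",
                           paste(unique(cn$ref[duplicated(cn$ref)]), collapse = ", ")))
  if (nrow(cn) && !all(termNamespace(cn$ref) == cn$scheme))
    msgs <- c(msgs, "concept ref namespace inconsistent with its scheme")
  br <- object@broader
  if (nrow(br)) {
    missParent <- setdiff(br$parent, cn$ref)
    if (length(missParent))
      msgs <- c(msgs, paste0("broader target(s) not defined: ",
                             paste(missParent, collapse = ", ")))
    missChild <- setdiff(br$ref, cn$ref)
    if (length(missChild))
      msgs <- c(msgs, paste0("broader source(s) not defined: ",
                             paste(missChild, collapse = ", ")))
    if (nrow(br) && !length(missParent) && !length(missChild)) {
      g <- igraph::graph_from_data_frame(br, directed = TRUE)
      if (!igraph::is_dag(g)) {
        cyc <- findBroaderCycle(br)
        msgs <- c(msgs, paste0("broader hierarchy contains a cycle: ",
                               paste(cyc, collapse = " -> ")))
      }
    }
  }
  cm <- object@closeMatch
  if (nrow(cm)) {
    key <- paste(cm$ref, cm$match)
    rev <- paste(cm$match, cm$ref)
    if (!all(rev %in% key))
      msgs <- c(msgs, "closeMatch is not symmetric")
  }
  if (length(object@collections)) {
    nm <- names(object@collections)
    if (is.null(nm) || any(nm == "") || any(termNamespace(nm) != "cc"))
      msgs <- c(msgs, "collection names must be cc: refs")
    if (any(lengths(object@collections) == 0L))
      msgs <- c(msgs, "collections must have at least one member")
  }
  if (length(msgs)) msgs else TRUE
})

## walk parent pointers to exhibit one cycle for the error message
findBroaderCycle <- function(br) {
  adj <- split(br$parent, br$ref)
  for (start in names(adj)) {
    path <- start
    repeat {
      nxt <- adj[[path[length(path)]]]
      if (is.null(nxt)) break
      nxt <- nxt[[1L]]
      if (nxt %in% path)
        return(c(path[which(path == nxt):length(path)], nxt))
      if (length(path) > length(adj)) break
      path <- c(path, nxt)
    }
  }
  character(0)
}

#' Patient and enriched patient records
#'
#' A `Patient` holds the asserted coded record: diseases and currently taken
#' drugs/substances (`data`), plus the demographic age and sex groups that rule
#' constraints refer to. An `EnrichedPatient` is a patient closed under
#' terminology inference (see [enrichPatient()]): `inferred` holds every term
#' implied by the asserted ones (hierarchy ancestors, triggered collections,
#' closeMatch equivalents), disjoint from the asserted set, and `provenance`
#' records which inference generator first produced each inferred term
#' (`"ancestor"`, `"collection"` or `"equivalence"`).
#'
#' @slot id character patient identifier.
#' @slot data character vector of asserted TermRefs.
#' @slot ageGroup one of `"child"`, `"adult"`, `"elder"`, `"any"`.
#' @slot sexGroup one of `"male"`, `"female"`, `"any"`.
#' @aliases EnrichedPatient-class
#' @seealso [patient()], [enrichPatient()], [allTerms()]
#' @export
setClass("Patient",
  representation(id = "character", data = "character",
                 ageGroup = "character", sexGroup = "character"))

setValidity("Patient", function(object) {
  msgs <- character(0)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msgs <- c(msgs, "id must be a single non-empty string")
  if (length(object@data) && !all(isTermRef(object@data)))
    msgs <- c(msgs, "data contains invalid TermRefs")
  if (anyDuplicated(object@data))
    msgs <- c(msgs, "data contains duplicated refs")
  if (!identical(length(object@ageGroup), 1L) ||
      !object@ageGroup %in% RXR_AGE_GROUPS)
    msgs <- c(msgs, paste0("ageGroup must be one of ",
                           paste(RXR_AGE_GROUPS, collapse = ", ")))
  if (!identical(length(object@sexGroup), 1L) ||
      !object@sexGroup %in% RXR_SEX_GROUPS)
    msgs <- c(msgs, paste0("sexGroup must be one of ",
                           paste(RXR_SEX_GROUPS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @rdname Patient-class
#' @slot patient the base [Patient-class] record.
#' @slot inferred character vector of inferred TermRefs, disjoint from the
#'   asserted data.
#' @slot provenance named character vector mapping each inferred term to the
#'   generator that produced it.
#' @export
setClass("EnrichedPatient",
  representation(patient = "Patient", inferred = "character",
                 provenance = "character"))

setValidity("EnrichedPatient", function(object) {
  msgs <- character(0)
  if (length(intersect(object@inferred, object@patient@data)))
    msgs <- c(msgs, "inferred terms must be disjoint from asserted data")
  if (!setequal(names(object@provenance), object@inferred))
    msgs <- c(msgs, "provenance must cover exactly the inferred terms")
  if (length(object@provenance) &&
      !all(object@provenance %in% c("ancestor", "collection", "equivalence")))
    msgs <- c(msgs, "unknown provenance generator label")
  if (length(msgs)) msgs else TRUE
})

#' Medical rules and rule bases
#'
#' A `MedicalRule` is one parsed indication or contraindication: it licenses
#' (`polarity = "indication"`, the canTake side) or excludes
#' (`polarity = "contraindication"`, the cannotTake side) a substance for
#' patients whose enriched record satisfies the boolean premise expression and
#' whose age/sex group match the rule's demographic constraints. The premise
#' expression is a positive and/or tree over TermRefs -- there is no negation,
#' which is what makes premise-overlap rule selection sound.
#'
#' The expression AST is a nested list: `list(kind = "atom", ref = <TermRef>)`
#' or `list(kind = "and"|"or", children = <list of >= 2 subtrees>)`.
#'
#' A `RuleBase` is an ordered list of rules with unique ids plus a free-form
#' version string. OR-free conjunctive expansion is computed on demand by
#' [expandRule()] / [expandRuleBase()].
#'
#' @slot ruleId character, unique within a rule base.
#' @slot substance `sub:` TermRef the rule recommends or excludes.
#' @slot polarity `"indication"` or `"contraindication"`.
#' @slot expr premise AST (see Details).
#' @slot ageGroups,sexGroups character sets of allowed groups; `"any"` matches
#'   every patient.
#' @aliases RuleBase-class
#' @seealso [parseRule()], [expandRule()], [readRuleBase()]
#' @export
setClass("MedicalRule",
  representation(ruleId = "character", substance = "character",
                 polarity = "character", expr = "list",
                 ageGroups = "character", sexGroups = "character"))

setValidity("MedicalRule", function(object) {
  msgs <- character(0)
  if (length(object@substance) != 1L || termNamespace(object@substance) != "sub")
    msgs <- c(msgs, "substance must be a single sub: ref")
  if (!object@polarity %in% c("indication", "contraindication"))
    msgs <- c(msgs, "polarity must be indication or contraindication")
  if (!length(object@ageGroups) || !all(object@ageGroups %in% RXR_AGE_GROUPS))
    msgs <- c(msgs, "invalid ageGroups")
  if (!length(object@sexGroups) || !all(object@sexGroups %in% RXR_SEX_GROUPS))
    msgs <- c(msgs, "invalid sexGroups")
  ok <- tryCatch({ checkExprAST(object@expr); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (length(msgs)) msgs else TRUE
})

checkExprAST <- function(expr) {
  if (!is.list(expr) || is.null(expr$kind))
    stop("expression node must be a list with a 'kind'")
  switch(expr$kind,
    atom = {
      if (!isTermRef(expr$ref %||% "")) stop("atom without valid ref")
    },
    and = ,
    or = {
      if (length(expr$children %||% list()) < 2L)
        stop(expr$kind, " node needs >= 2 children")
      lapply(expr$children, checkExprAST)
    },
    stop("unknown node kind: ", expr$kind)
  )
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname MedicalRule-class
#' @slot rules list of [MedicalRule-class] objects.
#' @slot version character version tag for the rule dialect / base.
#' @export
setClass("RuleBase",
  representation(rules = "list", version = "character"),
  prototype(rules = list(), version = "1"))

setValidity("RuleBase", function(object) {
  if (length(object@rules)) {
    if (!all(vapply(object@rules, is, logical(1), "MedicalRule")))
      return("rules must all be MedicalRule objects")
    ids <- vapply(object@rules, function(r) r@ruleId, character(1))
    if (anyDuplicated(ids))
      return(paste0("duplicate rule id(s): ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  TRUE
})

#' RecommendationSet: the result of rule-based recommendation
#'
#' Aggregated output of [recommend()]: the substances licensed by at least one
#' fired indication rule (`canTake`), those excluded by at least one fired
#' contraindication rule (`cannotTake`), and the precedence-filtered final
#' recommendation list `final = canTake \ cannotTake` -- a contraindication
#' always wins over an indication for the same substance. `fired` keeps
#' per-rule provenance (which rule fired on which matched premises) for
#' auditability, and `trace` records the two-phase selection funnel sizes.
#'
#' @slot canTake,cannotTake,final sorted character vectors of `sub:` refs.
#' @slot fired data.frame with columns `rule_id`, `conjunct`, `substance`,
#'   `polarity`, `matched_premises` (list column).
#' @slot trace named list with `total_rules`, `candidate_set_size`,
#'   `final_set_size`, `selected_ids`, `strategy`.
#' @seealso [recommend()], [queryRecommendations()]
#' @export
setClass("RecommendationSet",
  representation(canTake = "character", cannotTake = "character",
                 final = "character", fired = "data.frame", trace = "list"))

setValidity("RecommendationSet", function(object) {
  msgs <- character(0)
  if (!setequal(object@final, setdiff(object@canTake, object@cannotTake)))
    msgs <- c(msgs, "final must equal canTake minus cannotTake")
  if (length(intersect(object@final, object@cannotTake)))
    msgs <- c(msgs, "final must not intersect cannotTake")
  if (nrow(object@fired)) {
    ind <- unique(object@fired$substance[object@fired$polarity == "indication"])
    con <- unique(object@fired$substance[object@fired$polarity == "contraindication"])
    if (!setequal(object@canTake, ind) || !setequal(object@cannotTake, con))
      msgs <- c(msgs, "canTake/cannotTake must be witnessed by fired rules")
  } else if (length(object@canTake) || length(object@cannotTake)) {
    msgs <- c(msgs, "non-empty recommendation without fired-rule witnesses")
  }
  if (length(msgs)) msgs else TRUE
})
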
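#' Construct a Patient record
#'
#' @param id patient identifier.
#' @param data character vector of asserted TermRefs (diagnosed diseases and
#'   currently taken drugs/substances).
#' @param ageGroup one of `"child"`, `"adult"`, `"elder"`, `"any"`.
#' @param sexGroup one of `"male"`, `"female"`, `"any"`.
#' @return a [Patient-class].
#' @examples
#' patient("p1", c("icd:D69.6"), "adult", "male")
#' @export
patient <- function(id, data, ageGroup = "any", sexGroup = "any") {
  p <- new("Patient", id = as.character(id),
           data = unique(termRef(data)),
           ageGroup = as.character(ageGroup), sexGroup = as.character(sexGroup))
  validObject(p)
  p
}

#' Transitive ancestors of a concept
#'
#' All concepts reachable from `ref` by following direct `broader` edges
#' upward -- the broader-transitive closure, excluding `ref` itself. This is
#' the inference-layer counterpart of the stored direct edges: e.g. on an
#' ICD-10 fragment where D69.6 sits under D69 under block D65-D69 under
#' chapter D50-D89, `ancestors("icd:D69.6", g)` is
#' `{icd:D69, icd:D65-D69, icd:D50-D89}`.
#'
#' @param ref a TermRef present in the graph.
#' @param graph a [ConceptGraph-class].
#' @return sorted character vector of ancestor refs (empty for a root).
#' @export
ancestors <- function(ref, graph) {
  stopifnot(is(graph, "ConceptGraph"))
  ref <- termRef(ref)
  if (!ref %in% concepts(graph)$ref)
    validationStop("unknown concept: ", ref)
  termSet(ancestorsInternal(ref, broaderIndex(graph)))
}

## parent adjacency as a named list for fast repeated lookup
broaderIndex <- function(graph) {
  br <- broaderEdges(graph)
  split(br$parent, factor(br$ref, levels = unique(br$ref)))
}

## BFS over parent pointers; `idx` from broaderIndex()
ancestorsInternal <- function(refs, idx) {
  seen <- character(0)
  frontier <- refs
  while (length(frontier)) {
    parents <- unique(unlist(idx[frontier], use.names = FALSE))
    frontier <- setdiff(parents, c(seen, refs))
    seen <- c(seen, frontier)
  }
  seen
}

## closeMatch adjacency
closeMatchIndex <- function(graph) {
  cm <- closeMatches(graph)
  split(cm$match, factor(cm$ref, levels = unique(cm$ref)))
}

#' Enrich a patient with all implied terminology terms
#'
#' The first reasoning layer. Starting from the asserted record, the enriched
#' term set is the least fixpoint under three generators, applied until
#' nothing new appears:
#'
#' 1. **ancestor** -- every broader-transitive ancestor of a held term;
#' 2. **collection** -- every custom concept collection whose *resolved*
#'    member set (see [resolveCollection()]) intersects the held terms is
#'    added, by name, as a held term (collections are never expanded downward:
#'    that would assert conditions the patient does not have);
#' 3. **equivalence** -- every closeMatch partner of a held term (chains close
#'    transitively through the fixpoint).
#'
#' For a patient asserted with `icd:D69.6` on a graph where the collection
#' `cc:deficiency-bone-marrow` lists D69.6 as a member, enrichment infers
#' `{icd:D69, icd:D65-D69, icd:D50-D89, cc:deficiency-bone-marrow}`.
#'
#' Enrichment is monotone and idempotent: re-enriching an enriched record adds
#' nothing. Provenance records, for each inferred term, the first generator
#' (in the order above) that produced it.
#'
#' @param p a [Patient-class]; every asserted ref must resolve against the
#'   graph (as a concept or a collection name), otherwise an error lists the
#'   offending refs.
#' @param graph a [ConceptGraph-class].
#' @return an [EnrichedPatient-class].
#' @seealso [allTerms()], [termMatches()]
#' @export
enrichPatient <- function(p, graph) {
  stopifnot(is(p, "Patient"), is(graph, "ConceptGraph"))
  known <- c(concepts(graph)$ref, names(collections(graph)))
  bad <- setdiff(p@data, known)
  if (length(bad))
    validationStop("patient ", p@id, " has unresolvable term(s): ",
                   paste(bad, collapse = ", "))
  bIdx <- broaderIndex(graph)
  cmIdx <- closeMatchIndex(graph)
  resolved <- resolveAllCollections(graph)

  terms <- p@data
  prov <- character(0)
  repeat {
    fromAnc <- ancestorsInternal(terms, bIdx)
    trig <- names(resolved)[vapply(resolved, function(m)
      any(m %in% terms), logical(1))]
    fromEq <- unique(unlist(cmIdx[intersect(terms, names(cmIdx))],
                            use.names = FALSE))
    added <- FALSE
    for (gen in c("ancestor", "collection", "equivalence")) {
      cand <- switch(gen, ancestor = fromAnc, collection = trig,
                     equivalence = fromEq)
      new <- setdiff(cand, c(terms, names(prov)))
      new <- setdiff(new, p@data)
      if (length(new)) {
        prov[new] <- gen
        added <- TRUE
      }
    }
    terms <- unique(c(terms, names(prov)))
    if (!added) break
  }
  inferred <- termSet(setdiff(terms, p@data))
  ep <- new("EnrichedPatient", patient = p, inferred = inferred,
            provenance = prov[inferred])
  validObject(ep)
  ep
}

#' Does a rule premise hold for an enriched patient?
#'
#' Exact normalized-TermRef membership of `premise` in the patient's enriched
#' term set -- all hierarchy/collection/equivalence generalisation has already
#' been folded into the enriched set, so evaluation is a plain set lookup.
#'
#' @param premise a TermRef.
#' @param ep an [EnrichedPatient-class].
#' @return logical scalar.
#' @export
termMatches <- function(premise, ep) {
  stopifnot(is(ep, "EnrichedPatient"))
  termRef(premise) %in% allTerms(ep)
}

#' Read / write patients as JSON
#'
#' The patient interchange format is
#' `{"id": str, "data": ["icd:D69.6", ...], "age_group": "adult",
#' "sex_group": "male"}`. `writeEnrichedPatient()` adds `"inferred"` and
#' `"provenance"` members.
#'
#' @param file JSON path.
#' @return `readPatient()`: a [Patient-class] (or list of them if the file
#'   holds a JSON array of records).
#' @export
readPatient <- function(file) {
  x <- jsonlite::fromJSON(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fromRec <- function(rec) {
    if (is.null(rec$id) || is.null(rec$data))
      validationStop("patient JSON needs 'id' and 'data'")
    patient(rec$id, unlist(rec$data),
            rec$age_group %||% "any", rec$sex_group %||% "any")
  }
  if (!is.null(x$id)) fromRec(x) else lapply(x, fromRec)
}

#' @rdname readPatient
#' @param p a [Patient-class].
#' @export
writePatient <- function(p, file) {
  stopifnot(is(p, "Patient"))
  jsonlite::write_json(
    list(id = p@id, data = p@data,
         age_group = p@ageGroup, sex_group = p@sexGroup),
    file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname readPatient
#' @param ep an [EnrichedPatient-class].
#' @export
writeEnrichedPatient <- function(ep, file = "") {
  stopifnot(is(ep, "EnrichedPatient"))
  txt <- jsonlite::toJSON(
    list(id = ep@patient@id, data = ep@patient@data,
         age_group = ep@patient@ageGroup, sex_group = ep@patient@sexGroup,
         inferred = ep@inferred, provenance = as.list(ep@provenance)),
    auto_unbox = TRUE, pretty = TRUE)
  if (nzchar(file)) writeLines(txt, file) else cat(txt, "\n")
  invisible(as.character(txt))
}
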
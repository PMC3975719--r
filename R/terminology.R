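#' Construct a ConceptGraph from component tables
#'
#' Low-level constructor used by the loaders; most users will call
#' [readTerminology()] instead. closeMatch pairs are symmetrised here, scheme
#' membership is derived from ref namespaces, and the result is validated
#' (duplicate refs, missing parents and broader cycles are errors; closeMatch
#' targets that are not defined concepts are flagged as dangling with a
#' warning).
#'
#' @param concepts data.frame with columns `ref`, `scheme`, `label`.
#' @param broader data.frame with columns `ref`, `parent`.
#' @param closeMatch data.frame with columns `ref`, `match` (any direction;
#'   symmetrised automatically).
#' @param collections named list of member character vectors.
#' @param schemes optional data.frame `id`, `title`; defaults to one scheme
#'   per namespace present.
#' @return a validated [ConceptGraph-class].
#' @export
conceptGraph <- function(concepts,
                         broader = NULL, closeMatch = NULL,
                         collections = list(), schemes = NULL) {
  concepts <- data.frame(ref = termRef(concepts$ref),
                         scheme = as.character(concepts$scheme),
                         label = as.character(concepts$label),
                         stringsAsFactors = FALSE)
  if (is.null(broader) || !nrow(broader)) {
    broader <- data.frame(ref = character(), parent = character(),
                          stringsAsFactors = FALSE)
  } else {
    broader <- data.frame(ref = termRef(broader$ref),
                          parent = termRef(broader$parent),
                          stringsAsFactors = FALSE)
    broader <- unique(broader)
  }
  if (is.null(closeMatch) || !nrow(closeMatch)) {
    closeMatch <- data.frame(ref = character(), match = character(),
                             stringsAsFactors = FALSE)
  } else {
    a <- termRef(closeMatch$ref); b <- termRef(closeMatch$match)
    closeMatch <- unique(data.frame(ref = c(a, b), match = c(b, a),
                                    stringsAsFactors = FALSE))
    closeMatch <- closeMatch[closeMatch$ref != closeMatch$match, , drop = FALSE]
    closeMatch <- closeMatch[order(closeMatch$ref, closeMatch$match), , drop = FALSE]
    rownames(closeMatch) <- NULL
  }
  if (is.null(schemes)) {
    ids <- sort(unique(concepts$scheme))
    schemes <- data.frame(id = ids, title = paste(toupper(ids), "scheme"),
                          stringsAsFactors = FALSE)
  }
  dangling <- termSet(setdiff(closeMatch$match, concepts$ref))
  if (length(dangling))
    warning("closeMatch target(s) not defined as concepts (kept, flagged dangling): ",
            paste(dangling, collapse = ", "), call. = FALSE)
  g <- new("ConceptGraph", concepts = concepts, broader = broader,
           closeMatch = closeMatch, collections = collections,
           schemes = schemes, dangling = dangling)
  validObject(g)
  g
}

#' Read a terminology TSV into a ConceptGraph
#'
#' The terminology dialect is a UTF-8 tab-separated file with a header row
#' `scheme  code  label  parent_code  equivalents`. Each row defines one
#' concept `scheme:code`; `parent_code` (optional) names the direct broader
#' concept *within the same scheme*; `equivalents` is a semicolon-separated
#' list of fully-qualified TermRefs declared closeMatch-equivalent to the row's
#' concept (e.g. a substance row with `atc:S01EC01`).
#'
#' Hierarchy comes exclusively from the explicit parent column -- the loader
#' never infers structure from code syntax (such as ICD-10 dotted codes),
#' which keeps it terminology-agnostic.
#'
#' @param file path to the TSV file (or a connection).
#' @return a validated [ConceptGraph-class] with no collections (attach those
#'   with [readCollections()]).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("scheme\tcode\tlabel\tparent_code\tequivalents",
#'              "icd\tD50-D89\tBlood diseases\t\t",
#'              "icd\tD69\tPurpura\tD50-D89\t"), tsv)
#' g <- readTerminology(tsv)
#' concepts(g)
#' @export
readTerminology <- function(file) {
  tab <- utils::read.delim(file, sep = "\t", quote = "", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           strip.white = FALSE, fileEncoding = "UTF-8")
  need <- c("scheme", "code", "label", "parent_code", "equivalents")
  if (!all(need %in% names(tab)))
    validationStop("terminology TSV must have columns: ",
                   paste(need, collapse = ", "))
  tab[is.na(tab)] <- ""  # ragged rows: absent trailing columns mean empty
  tab$scheme <- trimws(tab$scheme); tab$code <- trimws(tab$code)
  tab$parent_code <- trimws(tab$parent_code)
  badns <- setdiff(unique(tab$scheme), RXR_NAMESPACES)
  if (length(badns))
    validationStop("unknown scheme(s) in terminology TSV: ",
                   paste(badns, collapse = ", "))
  ref <- paste0(tab$scheme, ":", tab$code)
  dup <- ref[duplicated(ref)]
  if (length(dup))
    validationStop("duplicate code(s) within scheme: ",
                   paste(unique(dup), collapse = ", "))
  concepts <- data.frame(ref = ref, scheme = tab$scheme, label = tab$label,
                         stringsAsFactors = FALSE)
  hasParent <- which(nzchar(tab$parent_code))
  broader <- if (length(hasParent))
    data.frame(ref = ref[hasParent],
               parent = paste0(tab$scheme[hasParent], ":",
                               tab$parent_code[hasParent]),
               stringsAsFactors = FALSE)
  else data.frame(ref = character(), parent = character(),
                  stringsAsFactors = FALSE)
  missParent <- setdiff(broader$parent, ref)
  if (length(missParent))
    validationStop("parent_code references missing code(s): ",
                   paste(missParent, collapse = ", "))
  eqRows <- which(nzchar(trimws(tab$equivalents)))
  closeMatch <- NULL
  if (length(eqRows)) {
    pieces <- strsplit(tab$equivalents[eqRows], ";", fixed = TRUE)
    closeMatch <- data.frame(
      ref = rep(ref[eqRows], lengths(pieces)),
      match = termRef(unlist(pieces)),
      stringsAsFactors = FALSE)
  }
  tryCatch(
    conceptGraph(concepts, broader, closeMatch),
    error = function(e) validationStop("terminology validation failed: ",
                                       conditionMessage(e)))
}

#' Write a ConceptGraph back to the terminology TSV dialect
#'
#' Inverse of [readTerminology()] for the concept/hierarchy/equivalence part
#' of a graph (collections live in their own file; see [writeCollections()]).
#' A concept with several parents gets one row per parent (the loader merges
#' them back). Each closeMatch pair is emitted once, on the
#' lexicographically-first endpoint's row.
#'
#' @param graph a [ConceptGraph-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTerminology <- function(graph, file) {
  stopifnot(is(graph, "ConceptGraph"))
  cn <- concepts(graph); br <- broaderEdges(graph); cm <- closeMatches(graph)
  cm <- cm[cm$ref < cm$match, , drop = FALSE]  # one line per pair
  lines <- "scheme\tcode\tlabel\tparent_code\tequivalents"
  for (i in seq_len(nrow(cn))) {
    r <- cn$ref[i]
    parents <- br$parent[br$ref == r]
    eqs <- paste(cm$match[cm$ref == r], collapse = ";")
    pcol <- if (length(parents)) termLocal(parents) else ""
    first <- TRUE
    for (p in pcol) {
      lines <- c(lines, paste(cn$scheme[i], termLocal(r), cn$label[i], p,
                              if (first) eqs else "", sep = "\t"))
      first <- FALSE
    }
  }
  writeLines(enc2utf8(lines), file, useBytes = TRUE)
  invisible(file)
}

#' Read custom concept collection definitions
#'
#' Custom concept collections ("conditions") are expert-defined named unions
#' of codes and/or other collections, used as single rule premises -- e.g.
#'
#' ```
#' cardiac-rhythm-abnormalities = cc:bradycardia | icd:R00 | cc:tachycardia | icd:O68.0 | icd:O68.2
#' ```
#'
#' The file is UTF-8 text with `#` comments; one `name = term | term | ...`
#' per line. Names are `cc:` refs (the `cc:` prefix on the left-hand side is
#' optional). Forward references to collections defined later in the file are
#' allowed -- nesting is only checked at resolution time
#' ([resolveCollection()]). Duplicate members within one definition are
#' removed with a warning; redefining a name is an error.
#'
#' @param file path to the collections file.
#' @param graph the [ConceptGraph-class] to attach the collections to.
#' @return the graph with collections attached.
#' @seealso [resolveCollection()]
#' @export
readCollections <- function(file, graph) {
  stopifnot(is(graph, "ConceptGraph"))
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  colls <- collections(graph)
  for (i in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(raw))) next
    eq <- regexpr("=", raw, fixed = TRUE)
    if (eq < 0)
      validationStop("collections line ", i, ": expected 'name = term | ...'")
    name <- trimws(substr(raw, 1L, eq - 1L))
    if (!grepl(":", name, fixed = TRUE)) name <- paste0("cc:", name)
    name <- tryCatch(termRef(name), error = function(e)
      validationStop("collections line ", i, ": ", conditionMessage(e)))
    if (termNamespace(name) != "cc")
      validationStop("collections line ", i,
                     ": collection names must be in the cc namespace")
    if (name %in% names(colls))
      validationStop("collections line ", i, ": redefinition of ", name)
    memStr <- trimws(strsplit(substr(raw, eq + 1L, nchar(raw)), "|",
                              fixed = TRUE)[[1]])
    if (!length(memStr) || any(!nzchar(memStr)))
      validationStop("collections line ", i, ": empty member in definition of ",
                     name)
    members <- tryCatch(termRef(memStr), error = function(e)
      validationStop("collections line ", i, ": ", conditionMessage(e)))
    if (anyDuplicated(members)) {
      warning("collections line ", i, ": duplicate member(s) in ", name,
              " removed", call. = FALSE)
      members <- members[!duplicated(members)]
    }
    colls[[name]] <- members
  }
  g <- graph
  g@collections <- colls
  validObject(g)
  g
}

#' Write collection definitions in the `name = t1 | t2 | ...` dialect
#'
#' @param graph a [ConceptGraph-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeCollections <- function(graph, file) {
  stopifnot(is(graph, "ConceptGraph"))
  colls <- collections(graph)
  lines <- vapply(names(colls), function(nm)
    paste(termLocal(nm), "=", paste(colls[[nm]], collapse = " | ")),
    character(1))
  writeLines(enc2utf8(lines), file, useBytes = TRUE)
  invisible(file)
}

#' Resolve a collection to its flattened member set
#'
#' Recursively substitutes nested collection references until only
#' non-collection TermRefs remain; duplicates are merged. E.g. with the
#' definitions `bradycardia = icd:I49.5 | icd:R00.1 | icd:O68.0` and
#' `tachycardia = icd:R00.0 | icd:I49.5 | icd:I47 | icd:O68.0`, resolving
#' `cc:cardiac-rhythm-abnormalities = cc:bradycardia | icd:R00 |
#' cc:tachycardia | icd:O68.0 | icd:O68.2` yields the seven codes
#' `{icd:I47, icd:I49.5, icd:O68.0, icd:O68.2, icd:R00, icd:R00.0, icd:R00.1}`.
#'
#' A cycle among collections, or a `cc:` member that is neither a defined
#' collection nor a defined concept, is an error (collections feed rule
#' premises and must be sound). Resolution is idempotent and independent of
#' member order.
#'
#' @param name the `cc:` ref of a loaded collection.
#' @param graph a [ConceptGraph-class] with collections attached.
#' @return sorted character vector of non-collection TermRefs.
#' @export
resolveCollection <- function(name, graph) {
  stopifnot(is(graph, "ConceptGraph"))
  name <- termRef(name)
  colls <- collections(graph)
  if (!name %in% names(colls))
    validationStop("unknown collection: ", name)
  knownConcepts <- concepts(graph)$ref
  resolveRec <- function(nm, stack) {
    if (nm %in% stack)
      validationStop("cycle among collections: ",
                     paste(c(stack[which(stack == nm):length(stack)], nm),
                           collapse = " -> "))
    out <- character(0)
    for (m in colls[[nm]]) {
      if (m %in% names(colls)) {
        out <- c(out, resolveRec(m, c(stack, nm)))
      } else if (termNamespace(m) == "cc" && !m %in% knownConcepts) {
        validationStop("collection ", nm, " references missing collection ", m)
      } else {
        out <- c(out, m)
      }
    }
    out
  }
  termSet(resolveRec(name, character(0)))
}

#' Resolve every collection in a graph at once
#'
#' @param graph a [ConceptGraph-class].
#' @return named list mapping each collection ref to its resolved member set.
#' @export
resolveAllCollections <- function(graph) {
  nms <- names(collections(graph))
  stats::setNames(lapply(nms, resolveCollection, graph = graph), nms)
}
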
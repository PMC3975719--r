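## SKOS Turtle import/export.
##
## The dialect is deliberately small: concepts, schemes and collections are
## typed skos:Concept / skos:ConceptScheme / skos:Collection, and exactly four
## SKOS properties carry the content -- skos:prefLabel (labels),
## skos:broaderTransitive (direct hierarchy edges; transitive closure is an
## inference-time notion, so only direct parent edges are ever serialized),
## skos:closeMatch (equivalences) and skos:member (collection membership).

RXR_SKOS_IRI <- "http://www.w3.org/2004/02/skos/core#"
RXR_BASE_IRI <- "http://rxreasoner.org/"
RXR_NS_IRI <- function(ns) paste0(RXR_BASE_IRI, "terminology/", ns, "#")
RXR_FRAMEWORK_IRI <- paste0(RXR_BASE_IRI, "ns#")

ttlSafeLocal <- function(x) {
  grepl("^[A-Za-z0-9][A-Za-z0-9._-]*$", x) & !grepl("\\.$", x)
}

ttlTerm <- function(ref) {
  ns <- termNamespace(ref); local <- termLocal(ref)
  ifelse(ttlSafeLocal(local),
         paste0(ns, ":", local),
         paste0("<", RXR_NS_IRI(ns), utils::URLencode(local, reserved = TRUE), ">"))
}

ttlLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

#' Write a ConceptGraph as SKOS Turtle
#'
#' Serializes the graph using the SKOS vocabulary: each concept becomes a
#' `skos:Concept` with a `skos:prefLabel` and one `skos:broaderTransitive`
#' triple per *direct* parent edge (transitivity is left to the inference
#' layer), closeMatch pairs become `skos:closeMatch` triples (both stored
#' directions are emitted), schemes become `skos:ConceptScheme` nodes and
#' collections `skos:Collection` nodes with ordered `skos:member` objects.
#'
#' [readSKOS()] inverts this exactly: read-after-write is the identity on
#' concepts, labels, broader edges, closeMatch pairs, schemes and collection
#' membership.
#'
#' @param graph a validated [ConceptGraph-class].
#' @param file output path for the Turtle document.
#' @return `file`, invisibly.
#' @export
writeSKOS <- function(graph, file) {
  stopifnot(is(graph, "ConceptGraph"))
  validObject(graph)
  cn <- concepts(graph); br <- broaderEdges(graph); cm <- closeMatches(graph)
  colls <- collections(graph); sch <- schemes(graph)
  usedNs <- sort(unique(c(cn$scheme, termNamespace(names(colls)),
                          termNamespace(cm$match), termNamespace(br$parent))))
  out <- c(
    paste0("@prefix skos: <", RXR_SKOS_IRI, "> ."),
    paste0("@prefix rxr: <", RXR_FRAMEWORK_IRI, "> ."),
    vapply(usedNs, function(ns)
      paste0("@prefix ", ns, ": <", RXR_NS_IRI(ns), "> ."), character(1)),
    "")
  for (i in seq_len(nrow(sch))) {
    out <- c(out,
      paste0("rxr:scheme-", sch$id[i], " a skos:ConceptScheme ;"),
      paste0("    skos:prefLabel ", ttlLiteral(sch$title[i]), " ."),
      "")
  }
  for (i in seq_len(nrow(cn))) {
    r <- cn$ref[i]
    props <- paste0("    skos:prefLabel ", ttlLiteral(cn$label[i]))
    parents <- br$parent[br$ref == r]
    if (length(parents))
      props <- c(props, paste0("    skos:broaderTransitive ",
                               paste(ttlTerm(parents), collapse = " , ")))
    eqs <- cm$match[cm$ref == r]
    if (length(eqs))
      props <- c(props, paste0("    skos:closeMatch ",
                               paste(ttlTerm(eqs), collapse = " , ")))
    out <- c(out, paste0(ttlTerm(r), " a skos:Concept ;"),
             paste0(props, c(rep(" ;", length(props) - 1L), " .")), "")
  }
  for (nm in names(colls)) {
    out <- c(out, paste0(ttlTerm(nm), " a skos:Collection ;"),
             paste0("    skos:member ",
                    paste(ttlTerm(colls[[nm]]), collapse = " , "), " ."),
             "")
  }
  writeLines(enc2utf8(out), file, useBytes = TRUE)
  invisible(file)
}

## --- minimal Turtle tokenizer/parser for the dialect written above ---------

ttlTokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- vector("list", 0L)
  i <- 1L
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L; next }
    if (ch %in% c(".", ";", ",")) { push("punct", ch); i <- i + 1L; next }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("unterminated IRI in Turtle input")
      push("iri", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L; buf <- character(0)
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\\") {
          j <- j + 1L
          buf <- c(buf, switch(chars[j], n = "\n", r = "\r", t = "\t",
                               "\\" = "\\", "\"" = "\"", chars[j]))
        } else buf <- c(buf, chars[j])
        j <- j + 1L
      }
      if (j > n) stop("unterminated string literal in Turtle input")
      push("literal", paste(buf, collapse = ""))
      i <- j + 1L; next
    }
    ## bare word: @prefix, 'a', or prefixed name
    j <- i
    while (j <= n && !chars[j] %in% c(" ", "\t", "\n", "\r", ";", ",", "<", "\"") &&
           !(chars[j] == "." && (j == n || chars[j + 1L] %in% c(" ", "\t", "\n", "\r"))))
      j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    if (word == "@prefix") push("atprefix", word)
    else if (word == "a") push("a", word)
    else if (grepl("^[A-Za-z][A-Za-z0-9_-]*:", word)) push("pname", word)
    else stop("unexpected token in Turtle input: ", sQuote(word))
    i <- j
  }
  toks
}

ttlResolve <- function(tok, prefixes) {
  if (tok$type == "iri") return(tok$value)
  if (tok$type == "a") return("rdf:type")
  if (tok$type == "pname") {
    p <- sub(":.*$", "", tok$value)
    local <- sub("^[^:]*:", "", tok$value)
    base <- prefixes[[p]]
    if (is.null(base)) stop("undeclared prefix: ", p)
    return(paste0(base, local))
  }
  stop("expected IRI or prefixed name, got ", tok$type)
}

## full IRI back to a TermRef (or scheme id, or skos property shorthand)
iriToRef <- function(iri) {
  for (ns in RXR_NAMESPACES) {
    base <- RXR_NS_IRI(ns)
    if (startsWith(iri, base))
      return(termRef(paste0(ns, ":",
                            utils::URLdecode(substring(iri, nchar(base) + 1L)))))
  }
  NA_character_
}

#' Read a SKOS Turtle document into a ConceptGraph
#'
#' Parses the Turtle dialect emitted by [writeSKOS()]: `skos:Concept`,
#' `skos:ConceptScheme` and `skos:Collection` typed subjects carrying
#' `skos:prefLabel`, `skos:broaderTransitive`, `skos:closeMatch` and
#' `skos:member` triples. Triples with an unknown property raise a warning and
#' are skipped; a subject carrying SKOS properties but no recognised type is
#' an error.
#'
#' @param file path to a Turtle document.
#' @return a validated [ConceptGraph-class].
#' @export
readSKOS <- function(file) {
  text <- paste(readLines(file, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  toks <- ttlTokenize(text)
  prefixes <- list()
  triples <- list()
  i <- 1L
  ntok <- length(toks)
  expectPunct <- function(i, what) {
    if (i > ntok || toks[[i]]$type != "punct" || toks[[i]]$value != what)
      stop("malformed Turtle: expected '", what, "'")
    i + 1L
  }
  while (i <= ntok) {
    if (toks[[i]]$type == "atprefix") {
      pname <- toks[[i + 1L]]
      iri <- toks[[i + 2L]]
      if (pname$type != "pname" && !(pname$type == "punct"))
        stop("malformed @prefix declaration")
      label <- sub(":$", "", pname$value)
      prefixes[[label]] <- iri$value
      i <- expectPunct(i + 3L, ".")
      next
    }
    subj <- ttlResolve(toks[[i]], prefixes); i <- i + 1L
    repeat {
      pred <- ttlResolve(toks[[i]], prefixes); i <- i + 1L
      repeat {
        objTok <- toks[[i]]; i <- i + 1L
        obj <- if (objTok$type == "literal") objTok$value
               else ttlResolve(objTok, prefixes)
        triples[[length(triples) + 1L]] <-
          list(s = subj, p = pred, o = obj, lit = objTok$type == "literal")
        if (i <= ntok && toks[[i]]$type == "punct" && toks[[i]]$value == ",") {
          i <- i + 1L
        } else break
      }
      if (i <= ntok && toks[[i]]$type == "punct" && toks[[i]]$value == ";") {
        i <- i + 1L
        ## tolerate a trailing ';' before the closing '.'
        if (i <= ntok && toks[[i]]$type == "punct" && toks[[i]]$value == ".") break
      } else break
    }
    i <- expectPunct(i, ".")
  }
  skosProp <- function(name) paste0(RXR_SKOS_IRI, name)
  types <- list(); labels <- list(); parents <- list()
  matches <- list(); members <- list()
  for (tr in triples) {
    if (tr$p == "rdf:type") {
      types[[tr$s]] <- c(types[[tr$s]], tr$o)
    } else if (tr$p == skosProp("prefLabel")) {
      labels[[tr$s]] <- tr$o
    } else if (tr$p == skosProp("broaderTransitive")) {
      parents[[tr$s]] <- c(parents[[tr$s]], tr$o)
    } else if (tr$p == skosProp("closeMatch")) {
      matches[[tr$s]] <- c(matches[[tr$s]], tr$o)
    } else if (tr$p == skosProp("member")) {
      members[[tr$s]] <- c(members[[tr$s]], tr$o)
    } else {
      warning("skipping triple with unknown property: ", tr$p, call. = FALSE)
    }
  }
  typeOf <- function(s) {
    t <- types[[s]]
    if (is.null(t)) stop("subject without SKOS typing: ", s)
    if (skosProp("Concept") %in% t) "concept"
    else if (skosProp("ConceptScheme") %in% t) "scheme"
    else if (skosProp("Collection") %in% t) "collection"
    else stop("subject without recognised SKOS typing: ", s)
  }
  subjects <- unique(vapply(triples, function(tr) tr$s, character(1)))
  conceptRows <- list(); schemeRows <- list(); broaderRows <- list()
  cmRows <- list(); colls <- list()
  for (s in subjects) {
    kind <- typeOf(s)
    if (kind == "scheme") {
      id <- sub(paste0("^", RXR_FRAMEWORK_IRI, "scheme-"), "", s)
      schemeRows[[s]] <- data.frame(id = id, title = labels[[s]] %||% "",
                                    stringsAsFactors = FALSE)
    } else if (kind == "concept") {
      ref <- iriToRef(s)
      if (is.na(ref)) stop("concept IRI outside known namespaces: ", s)
      conceptRows[[s]] <- data.frame(ref = ref, scheme = termNamespace(ref),
                                     label = labels[[s]] %||% "",
                                     stringsAsFactors = FALSE)
      for (p in parents[[s]])
        broaderRows[[length(broaderRows) + 1L]] <-
          data.frame(ref = ref, parent = iriToRef(p), stringsAsFactors = FALSE)
      for (m in matches[[s]])
        cmRows[[length(cmRows) + 1L]] <-
          data.frame(ref = ref, match = iriToRef(m), stringsAsFactors = FALSE)
    } else {
      nm <- iriToRef(s)
      colls[[nm]] <- vapply(members[[s]], iriToRef, character(1), USE.NAMES = FALSE)
    }
  }
  bind <- function(rows, empty) if (length(rows)) do.call(rbind, rows) else empty
  cn <- bind(unname(conceptRows),
             data.frame(ref = character(), scheme = character(),
                        label = character(), stringsAsFactors = FALSE))
  sch <- bind(unname(schemeRows),
              data.frame(id = character(), title = character(),
                         stringsAsFactors = FALSE))
  rownames(cn) <- NULL
  if (nrow(sch)) { sch <- sch[order(sch$id), , drop = FALSE]; rownames(sch) <- NULL }
  conceptGraph(cn,
               broader = bind(broaderRows, NULL),
               closeMatch = bind(cmRows, NULL),
               collections = colls,
               schemes = sch)
}
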
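#' Parse one medical rule line
#'
#' The rule dialect expresses drug indications and contraindications over
#' coded premises. Grammar (EBNF):
#'
#' ```
#' rule     = [ "[" rule-id "]" ] [ "!" ] substance "=" expr
#'            { "," demographic-clause } ;
#' expr     = term { "|" term } ;            (* | = or, lowest precedence *)
#' term     = factor { "&" factor } ;        (* & = and, binds tighter   *)
#' factor   = atom | "(" expr ")" ;
#' atom     = TermRef ;                      (* e.g. icd:E22.0, cc:bradycardia *)
#' demographic-clause = "ageGroup" "=" group { "or" group }
#'                    | "sexGroup" "=" group { "or" group } ;
#' ```
#'
#' A leading `!` marks a contraindication (the premises of a drug--drug
#' interaction are then drug/substance codes; a drug--disease
#' contraindication premises disease codes). Without `!` the rule is an
#' indication. The substance may be written bare (`lisuride`) or qualified
#' (`sub:lisuride`). Demographics default to `any`. Example -- the indication
#'
#' ```
#' lisuride = icd:E22.0 | (icd:E22.1 & (icd:N91.0 | icd:N97)), ageGroup=adult or elder
#' ```
#'
#' parses to `Or(E22.0, And(E22.1, Or(N91.0, N97)))` restricted to adult or
#' elder patients. `&` binds tighter than `|`; both associate left;
#' parentheses override. There is no negation operator: premises are positive
#' only, which keeps rule evaluation monotone and premise-overlap selection
#' sound.
#'
#' @param line a single rule line.
#' @param ruleId id to assign when the line carries no explicit `[id]`.
#' @return a [MedicalRule-class].
#' @seealso [expandRule()], [evaluateExpr()], [readRuleBase()]
#' @export
parseRule <- function(line, ruleId = "R0001") {
  stopifnot(is.character(line), length(line) == 1L)
  orig <- line
  perr <- function(col, ...) {
    validationStop("rule parse error at column ", col, ": ", ...,
                   "\n  in: ", trimws(orig))
  }
  ## optional [id] prefix
  line2 <- line
  m <- regmatches(line2, regexec("^\\s*\\[([^]]+)\\]\\s*", line2))[[1]]
  offset <- 0L
  if (length(m)) {
    ruleId <- trimws(m[2])
    offset <- nchar(m[1])
    line2 <- substring(line2, offset + 1L)
  }
  ## polarity
  polarity <- "indication"
  bang <- regexpr("^\\s*!", line2)
  if (bang > 0) {
    polarity <- "contraindication"
    offset <- offset + attr(bang, "match.length")
    line2 <- sub("^\\s*!", "", line2)
  }
  eq <- regexpr("=", line2, fixed = TRUE)
  if (eq < 0) perr(nchar(orig), "missing '='")
  lhs <- trimws(substr(line2, 1L, eq - 1L))
  if (!nzchar(lhs)) perr(offset + 1L, "missing substance name")
  if (grepl("[[:space:]]", lhs)) perr(offset + 1L, "substance name contains whitespace")
  substance <- if (grepl(":", lhs, fixed = TRUE)) {
    if (termNamespace(lhs) != "sub")
      perr(offset + 1L, "substance must be in the sub namespace, got ", sQuote(lhs))
    termRef(lhs)
  } else termRef(paste0("sub:", lhs))
  rhs <- substring(line2, eq + 1L)
  rhsOffset <- offset + eq
  ## split off demographic clauses at top-level commas (no commas in exprs)
  parts <- strsplit(rhs, ",", fixed = TRUE)[[1]]
  if (!length(parts) || !nzchar(trimws(parts[1])))
    perr(rhsOffset + 1L, "empty rule expression")
  expr <- parseExpr(parts[1], rhsOffset, perr)
  ageGroups <- NULL; sexGroups <- NULL
  clauseOffset <- rhsOffset + nchar(parts[1]) + 1L
  for (cl in parts[-1]) {
    cm <- regmatches(cl, regexec("^\\s*(ageGroup|sexGroup)\\s*=\\s*(.+?)\\s*$", cl))[[1]]
    if (!length(cm))
      perr(clauseOffset + 1L, "malformed demographic clause ", sQuote(trimws(cl)))
    groups <- trimws(strsplit(cm[3], "\\s+or\\s+")[[1]])
    if (cm[2] == "ageGroup") {
      if (!is.null(ageGroups)) perr(clauseOffset + 1L, "duplicate ageGroup clause")
      bad <- setdiff(groups, RXR_AGE_GROUPS)
      if (length(bad)) perr(clauseOffset + 1L, "unknown age group ", sQuote(bad[1]))
      ageGroups <- unique(groups)
    } else {
      if (!is.null(sexGroups)) perr(clauseOffset + 1L, "duplicate sexGroup clause")
      bad <- setdiff(groups, RXR_SEX_GROUPS)
      if (length(bad)) perr(clauseOffset + 1L, "unknown sex group ", sQuote(bad[1]))
      sexGroups <- unique(groups)
    }
    clauseOffset <- clauseOffset + nchar(cl) + 1L
  }
  r <- new("MedicalRule", ruleId = ruleId, substance = substance,
           polarity = polarity, expr = expr,
           ageGroups = ageGroups %||% "any", sexGroups = sexGroups %||% "any")
  validObject(r)
  r
}

## recursive-descent parser over the premise expression
parseExpr <- function(text, baseOffset, perr) {
  ## tokenize with positions
  toks <- list()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "|", "(", ")")) {
      toks[[length(toks) + 1L]] <- list(t = ch, col = baseOffset + i)
      i <- i + 1L
      next
    }
    m <- regexpr("^[^[:space:]()&|,]+", substring(text, i))
    word <- regmatches(substring(text, i), m)
    toks[[length(toks) + 1L]] <- list(t = "atom", v = word, col = baseOffset + i)
    i <- i + attr(m, "match.length")
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { tk <- peek(); pos <<- pos + 1L; tk }
  flatten <- function(kind, children) {
    ## left-assoc n-ary node; collapse single child
    if (length(children) == 1L) children[[1]]
    else list(kind = kind, children = children)
  }
  pFactor <- function() {
    tk <- take()
    if (is.null(tk)) perr(baseOffset + nchar(text), "unexpected end of expression")
    if (tk$t == "(") {
      e <- pOr()
      cl <- take()
      if (is.null(cl) || cl$t != ")")
        perr(tk$col, "unbalanced parenthesis opened here")
      return(e)
    }
    if (tk$t != "atom")
      perr(tk$col, "expected a term, got ", sQuote(tk$t))
    ref <- tryCatch(termRef(tk$v), error = function(e)
      perr(tk$col, conditionMessage(e)))
    list(kind = "atom", ref = ref)
  }
  pAnd <- function() {
    children <- list(pFactor())
    while (!is.null(peek()) && peek()$t == "&") {
      take()
      children[[length(children) + 1L]] <- pFactor()
    }
    flatten("and", children)
  }
  pOr <- function() {
    children <- list(pAnd())
    while (!is.null(peek()) && peek()$t == "|") {
      take()
      children[[length(children) + 1L]] <- pAnd()
    }
    flatten("or", children)
  }
  e <- pOr()
  left <- peek()
  if (!is.null(left))
    perr(left$col, "unexpected ",
         sQuote(if (left$t == "atom") left$v else left$t),
         if (left$t == ")") " (unbalanced parenthesis)" else "")
  e
}

## parentheses are emitted where precedence requires them (or under and) and
## where a same-kind child would otherwise flatten into its parent's chain,
## so parse(render(ast)) reproduces the AST node for node
renderExpr <- function(node, parent = "none") {
  switch(node$kind,
    atom = node$ref,
    or = {
      s <- paste(vapply(node$children, renderExpr, character(1), parent = "or"),
                 collapse = " | ")
      if (parent %in% c("and", "or")) paste0("(", s, ")") else s
    },
    and = {
      s <- paste(vapply(node$children, renderExpr, character(1), parent = "and"),
                 collapse = " & ")
      if (parent == "and") paste0("(", s, ")") else s
    }
  )
}

#' Render a rule back to its one-line dialect form
#'
#' Inverse of [parseRule()] up to whitespace: parentheses are emitted only
#' where precedence requires them, demographics only when not `any`, and the
#' substance is written bare. `parseRule(writeRuleLine(r))` reproduces an
#' identical AST.
#'
#' @param rule a [MedicalRule-class].
#' @param withId prefix the line with `[rule_id]`?
#' @return a character scalar.
#' @export
writeRuleLine <- function(rule, withId = FALSE) {
  stopifnot(is(rule, "MedicalRule"))
  line <- paste0(
    if (withId) paste0("[", rule@ruleId, "] ") else "",
    if (rule@polarity == "contraindication") "!" else "",
    termLocal(rule@substance), " = ", renderExpr(rule@expr))
  if (!identical(rule@ageGroups, "any"))
    line <- paste0(line, ", ageGroup=", paste(rule@ageGroups, collapse = " or "))
  if (!identical(rule@sexGroups, "any"))
    line <- paste0(line, ", sexGroup=", paste(rule@sexGroups, collapse = " or "))
  line
}

#' All atom refs of a premise expression
#'
#' @param expr a premise AST (see [MedicalRule-class]).
#' @return sorted character vector of the distinct TermRefs appearing as atoms.
#' @export
exprAtoms <- function(expr) {
  rec <- function(node) {
    if (node$kind == "atom") node$ref
    else unlist(lapply(node$children, rec), use.names = FALSE)
  }
  termSet(rec(expr))
}

#' Expand a rule into OR-free conjunctive rules
#'
#' Distributes AND over OR until the premise expression is a disjunction of
#' conjunctions, then emits one conjunctive rule per disjunct -- the classic
#' OR-elimination needed by rule engines whose language forbids disjunction in
#' a rule body. The lisuride example expands to 3 conjunctive rules with
#' premise sets `{E22.0}`, `{E22.1, N91.0}` and `{E22.1, N97}`.
#'
#' Premises are deduplicated within a conjunct and identical conjuncts are
#' merged (logically lossless; bounds the blow-up). Expansion order is
#' deterministic, left to right. Demographic constraints are inherited
#' unchanged from the parent rule. An expansion exceeding `cap` conjuncts
#' aborts with an error naming the rule.
#'
#' @param rule a [MedicalRule-class].
#' @param cap maximum number of conjuncts tolerated (default 10000).
#' @return a data.frame of conjunctive rules with columns `parent_id`,
#'   `conjunct` (1-based index), `substance`, `polarity`, and list columns
#'   `premises`, `age_groups`, `sex_groups`.
#' @examples
#' r <- parseRule(
#'   "lisuride = icd:E22.0 | (icd:E22.1 & (icd:N91.0 | icd:N97)), ageGroup=adult or elder")
#' expandRule(r)$premises
#' @export
expandRule <- function(rule, cap = 10000L) {
  stopifnot(is(rule, "MedicalRule"))
  conjuncts <- exprToDNF(rule@expr, cap, rule@ruleId)
  ## merge identical conjuncts, preserving first-occurrence order
  keys <- vapply(conjuncts, paste, character(1), collapse = "")
  conjuncts <- conjuncts[!duplicated(keys)]
  n <- length(conjuncts)
  data.frame(
    parent_id = rep(rule@ruleId, n),
    conjunct = seq_len(n),
    substance = rep(rule@substance, n),
    polarity = rep(rule@polarity, n),
    premises = I(conjuncts),
    age_groups = I(rep(list(rule@ageGroups), n)),
    sex_groups = I(rep(list(rule@sexGroups), n)),
    stringsAsFactors = FALSE)
}

## returns a list of premise sets (sorted unique character vectors),
## in deterministic left-to-right expansion order
exprToDNF <- function(expr, cap, ruleId) {
  rec <- function(node) {
    switch(node$kind,
      atom = list(node$ref),
      or = {
        out <- list()
        for (ch in node$children) {
          out <- c(out, rec(ch))
          if (length(out) > cap)
            validationStop("rule ", ruleId, ": OR-elimination exceeds ",
                           cap, " conjuncts")
        }
        out
      },
      and = {
        acc <- list(character(0))
        for (ch in node$children) {
          sub <- rec(ch)
          nxt <- vector("list", length(acc) * length(sub))
          k <- 0L
          for (a in acc) for (b in sub) {
            k <- k + 1L
            nxt[[k]] <- c(a, b)
          }
          if (length(nxt) > cap)
            validationStop("rule ", ruleId, ": OR-elimination exceeds ",
                           cap, " conjuncts")
          acc <- nxt
        }
        acc
      })
  }
  lapply(rec(expr), function(x) sort(unique(x), method = "radix"))
}

#' Expand every rule of a rule base
#'
#' @param rb a [RuleBase-class].
#' @param cap per-rule conjunct cap, as in [expandRule()].
#' @return the row-bound conjunctive-rule data.frame over all rules, in rule
#'   order.
#' @export
expandRuleBase <- function(rb, cap = 10000L) {
  stopifnot(is(rb, "RuleBase"))
  do.call(rbind, lapply(rb@rules, expandRule, cap = cap))
}

#' Evaluate a premise expression against an enriched patient
#'
#' Standard boolean semantics with atoms decided by [termMatches()] -- the
#' direct (un-expanded) evaluation strategy. For every rule and patient this
#' agrees exactly with "some expanded conjunct's premises are all held", which
#' is what makes the expanded and direct recommendation strategies
#' interchangeable.
#'
#' @param expr a premise AST.
#' @param ep an [EnrichedPatient-class], or a plain character vector of held
#'   terms.
#' @return logical scalar.
#' @export
evaluateExpr <- function(expr, ep) {
  terms <- if (is(ep, "EnrichedPatient")) allTerms(ep) else as.character(ep)
  rec <- function(node) {
    switch(node$kind,
      atom = node$ref %in% terms,
      and = all(vapply(node$children, rec, logical(1))),
      or = any(vapply(node$children, rec, logical(1))))
  }
  rec(expr)
}

#' Read / write a rule base file
#'
#' Line-oriented UTF-8 text: one rule per line in the [parseRule()] dialect,
#' `#` comments and blank lines ignored. A comment of the form
#' `# version: <tag>` sets the rule-base version. Rules without an explicit
#' `[id]` get ids `R0001`, `R0002`, ... in file order; a duplicate explicit id
#' is an error. `writeRuleBase()` emits explicit ids so that edits to one rule
#' never renumber the rest; read-after-write preserves every AST.
#'
#' @param file path to the rule file.
#' @return a [RuleBase-class].
#' @export
readRuleBase <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  version <- "1"
  rules <- list()
  autoN <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    vm <- regmatches(ln, regexec("^#\\s*version:\\s*(\\S+)", ln))[[1]]
    if (length(vm)) { version <- vm[2]; next }
    ln <- sub("(^|\\s)#.*$", "", ln)
    if (!nzchar(trimws(ln))) next
    autoN <- autoN + 1L
    r <- tryCatch(parseRule(ln, ruleId = sprintf("R%04d", autoN)),
                  error = function(e)
                    validationStop("rule file line ", i, ": ",
                                   conditionMessage(e)))
    rules[[length(rules) + 1L]] <- r
  }
  ids <- vapply(rules, function(r) r@ruleId, character(1))
  if (anyDuplicated(ids))
    validationStop("duplicate rule id(s): ",
                   paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rb <- new("RuleBase", rules = rules, version = version)
  validObject(rb)
  rb
}

#' @rdname readRuleBase
#' @param rb a [RuleBase-class].
#' @export
writeRuleBase <- function(rb, file) {
  stopifnot(is(rb, "RuleBase"))
  lines <- c(paste0("# version: ", rb@version),
             vapply(rb@rules, writeRuleLine, character(1), withId = TRUE))
  writeLines(enc2utf8(lines), file, useBytes = TRUE)
  invisible(file)
}

#' Assemble a RuleBase from parsed rules
#'
#' @param rules list of [MedicalRule-class] objects.
#' @param version version tag.
#' @return a [RuleBase-class].
#' @export
ruleBase <- function(rules, version = "1") {
  rb <- new("RuleBase", rules = rules, version = as.character(version))
  validObject(rb)
  rb
}
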
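# Independent oracles and small random-input builders shared across tests.
# The oracles deliberately use the most naive formulation available (single
# parent-pointer steps, plain recursion, exhaustive truth tables) so they
# share no code path with the package implementation they check.

## ancestors by iterated direct-parent lookup over the edge table
oracleAncestors <- function(ref, broader) {
  anc <- character(0)
  frontier <- ref
  repeat {
    parents <- unique(broader$parent[broader$ref %in% frontier])
    new <- setdiff(parents, c(anc, ref))
    if (!length(new)) break
    anc <- c(anc, new)
    frontier <- new
  }
  sort(anc)
}

## collection flattening by plain recursion over the definition list
oracleResolveColl <- function(name, colls) {
  out <- character(0)
  for (m in colls[[name]]) {
    if (m %in% names(colls)) out <- c(out, oracleResolveColl(m, colls))
    else out <- c(out, m)
  }
  sort(unique(out))
}

## enrichment by a naive one-step-generators-until-no-change loop
oracleEnrich <- function(data, graph) {
  colls <- collections(graph)
  br <- broaderEdges(graph)
  cm <- closeMatches(graph)
  resolved <- lapply(names(colls), oracleResolveColl, colls = colls)
  names(resolved) <- names(colls)
  terms <- data
  repeat {
    new <- c(br$parent[br$ref %in% terms],
             cm$match[cm$ref %in% terms],
             names(colls)[vapply(resolved, function(m) any(m %in% terms),
                                 logical(1))])
    new <- setdiff(unique(new), terms)
    if (!length(new)) break
    terms <- c(terms, new)
  }
  sort(setdiff(terms, data))
}

## truth-table evaluation of a premise AST under a set of true atoms
evalAssign <- function(expr, trueAtoms) {
  switch(expr$kind,
    atom = expr$ref %in% trueAtoms,
    and = all(vapply(expr$children, evalAssign, logical(1),
                     trueAtoms = trueAtoms)),
    or = any(vapply(expr$children, evalAssign, logical(1),
                    trueAtoms = trueAtoms)))
}

## a conjunct list satisfied under an assignment iff some conjunct is all-true
dnfSatisfied <- function(conjuncts, trueAtoms) {
  any(vapply(conjuncts, function(pr) all(pr %in% trueAtoms), logical(1)))
}

## random premise AST over a fixed atom pool
randExpr <- function(atoms, maxDepth = 4L) {
  gen <- function(depth) {
    if (depth >= maxDepth || runif(1) < 0.4)
      return(list(kind = "atom", ref = sample(atoms, 1L)))
    list(kind = sample(c("and", "or"), 1L),
         children = lapply(seq_len(sample(2:3, 1L)), function(i)
           gen(depth + 1L)))
  }
  ## force at least one operator so the expression is never a bare atom
  list(kind = sample(c("and", "or"), 1L),
       children = lapply(1:2, function(i) gen(2L)))
}

## random multi-parent DAG as a ConceptGraph (0-2 parents per node, all
## pointing at earlier nodes, so acyclicity holds by construction)
randDAG <- function(n, ns = "icd") {
  refs <- sprintf("%s:N%04d", ns, seq_len(n))
  rows <- list()
  for (i in seq_len(n)) {
    if (i == 1L) next
    k <- sample(0:2, 1L)
    if (k > 0L) {
      parents <- sample(seq_len(i - 1L), min(k, i - 1L))
      for (p in parents)
        rows[[length(rows) + 1L]] <-
          data.frame(ref = refs[i], parent = refs[p], stringsAsFactors = FALSE)
    }
  }
  conceptGraph(
    data.frame(ref = refs, scheme = ns, label = paste("node", seq_len(n)),
               stringsAsFactors = FALSE),
    broader = if (length(rows)) do.call(rbind, rows) else NULL)
}

## random acyclic nested collection system over a graph's icd codes:
## collection i may only reference collections < i
randCollectionSystem <- function(graph, nColl = 6L, maxDepth = 4L) {
  icd <- concepts(graph)$ref[concepts(graph)$scheme == "icd"]
  colls <- list()
  for (i in seq_len(nColl)) {
    members <- sample(icd, sample(1:4, 1L))
    if (length(colls) && runif(1) < 0.5)
      members <- c(members, sample(names(colls),
                                   min(length(colls), sample(1:2, 1L))))
    colls[[sprintf("cc:set%03d", i)]] <- unique(members)
  }
  g <- graph
  g@collections <- colls
  validObject(g)
  g
}

## structural equality of two concept graphs, order-insensitive
expectGraphsEqual <- function(g1, g2) {
  c1 <- concepts(g1); c1 <- c1[order(c1$ref), ]
  c2 <- concepts(g2); c2 <- c2[order(c2$ref), ]
  expect_equal(c1$ref, c2$ref)
  expect_equal(c1$label, c2$label)
  expect_equal(c1$scheme, c2$scheme)
  e1 <- broaderEdges(g1); e2 <- broaderEdges(g2)
  expect_setequal(paste(e1$ref, e1$parent), paste(e2$ref, e2$parent))
  m1 <- closeMatches(g1); m2 <- closeMatches(g2)
  expect_setequal(paste(m1$ref, m1$match), paste(m2$ref, m2$match))
  expect_setequal(as.character(names(collections(g1))),
                  as.character(names(collections(g2))))
  for (nm in names(collections(g1)))
    expect_equal(collections(g1)[[nm]], collections(g2)[[nm]], label = nm)
  s1 <- schemes(g1); s2 <- schemes(g2)
  expect_setequal(paste(s1$id, s1$title), paste(s2$id, s2$title))
}

## write lines to a tempfile, return the path
tmpText <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## recommendation triple for set-equality comparisons
recTriple <- function(rs) {
  list(can = canTake(rs), cannot = cannotTake(rs),
       final = finalRecommendations(rs))
}
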
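#' Specification for synthetic fixture generation
#'
#' A `fixtureSpec` pins down the shape of a synthetic terminology / collection
#' / rule-base / patient bundle. A single integer seed drives one PRNG stream
#' per generator (derived deterministically from the spec seed), so an
#' identical spec always yields byte-identical generated files -- no global
#' randomness is consumed or perturbed.
#'
#' @param seed integer master seed.
#' @param nConceptsPerScheme concepts generated per code scheme (a random
#'   forest for `icd` and `atc`, a flat substance list for `sub`).
#' @param maxDepth maximum hierarchy depth (root = depth 1).
#' @param nCollections number of custom concept collections.
#' @param collectionNestingDepth maximum collection-in-collection nesting.
#' @param nRules number of rules in the generated rule base.
#' @param orDensity probability, in `[0, 1]`, that an internal operator node
#'   of a generated premise expression is an OR (the rest are ANDs).
#' @param contraindicationFraction fraction of rules generated as
#'   contraindications; their premises mix drug and disease codes.
#' @param nPatients number of generated patients.
#' @param termsPerPatient integer range `c(min, max)` of asserted terms.
#' @return a classed list of the validated settings.
#' @export
fixtureSpec <- function(seed = 1L,
                        nConceptsPerScheme = 50L,
                        maxDepth = 4L,
                        nCollections = 10L,
                        collectionNestingDepth = 2L,
                        nRules = 100L,
                        orDensity = 0.5,
                        contraindicationFraction = 0.3,
                        nPatients = 20L,
                        termsPerPatient = c(2L, 6L)) {
  spec <- list(seed = as.integer(seed),
               nConceptsPerScheme = as.integer(nConceptsPerScheme),
               maxDepth = as.integer(maxDepth),
               nCollections = as.integer(nCollections),
               collectionNestingDepth = as.integer(collectionNestingDepth),
               nRules = as.integer(nRules),
               orDensity = as.numeric(orDensity),
               contraindicationFraction = as.numeric(contraindicationFraction),
               nPatients = as.integer(nPatients),
               termsPerPatient = as.integer(termsPerPatient))
  counts <- c("nConceptsPerScheme", "maxDepth", "nCollections",
              "collectionNestingDepth", "nRules", "nPatients")
  for (f in counts)
    if (spec[[f]] < 1L) validationStop(f, " must be >= 1")
  for (f in c("orDensity", "contraindicationFraction"))
    if (spec[[f]] < 0 || spec[[f]] > 1)
      validationStop(f, " must be in [0, 1]")
  if (length(spec$termsPerPatient) != 2L ||
      spec$termsPerPatient[1] < 1L ||
      spec$termsPerPatient[1] > spec$termsPerPatient[2])
    validationStop("termsPerPatient must be c(min, max) with 1 <= min <= max")
  structure(spec, class = "fixtureSpec")
}

## per-generator substreams of the master seed (kept < 2^31)
subSeed <- function(spec, k) (spec$seed * 101L + k) %% .Machine$integer.max

#' Generate a synthetic terminology graph
#'
#' Builds, deterministically under the spec seed, a random forest of
#' `nConceptsPerScheme` concepts for each of the `icd` and `atc` schemes
#' (depth bounded by `maxDepth`, multi-root), plus a flat `sub` substance
#' scheme (half the size) in which each substance is closeMatch-equivalent to
#' one ATC code -- emulating the substance \eqn{\equiv} ATC correspondence of
#' real drug dictionaries.
#'
#' @param spec a [fixtureSpec()].
#' @return a validated [ConceptGraph-class].
#' @export
genTerminology <- function(spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  withSeed(subSeed(spec, 1L), {
    conceptRows <- list(); broaderRows <- list(); cmRows <- list()
    for (ns in c("icd", "atc")) {
      n <- spec$nConceptsPerScheme
      refs <- sprintf("%s:%s%03d", ns, toupper(substr(ns, 1, 1)), seq_len(n))
      depth <- integer(n)
      for (i in seq_len(n)) {
        eligible <- which(depth[seq_len(i - 1L)] < spec$maxDepth)
        if (i == 1L || !length(eligible) || stats::runif(1) < 0.25) {
          depth[i] <- 1L  # new root
        } else {
          parent <- if (length(eligible) == 1L) eligible else
            sample(eligible, 1L)
          depth[i] <- depth[parent] + 1L
          broaderRows[[length(broaderRows) + 1L]] <-
            data.frame(ref = refs[i], parent = refs[parent],
                       stringsAsFactors = FALSE)
        }
      }
      conceptRows[[ns]] <- data.frame(
        ref = refs, scheme = ns,
        label = paste("Synthetic", ns, "concept", seq_len(n)),
        stringsAsFactors = FALSE)
    }
    nSub <- max(2L, spec$nConceptsPerScheme %/% 2L)
    subRefs <- sprintf("sub:substance%03d", seq_len(nSub))
    conceptRows[["sub"]] <- data.frame(
      ref = subRefs, scheme = "sub",
      label = paste("Synthetic substance", seq_len(nSub)),
      stringsAsFactors = FALSE)
    atcRefs <- conceptRows[["atc"]]$ref
    partner <- sample(atcRefs, nSub, replace = nSub > length(atcRefs))
    for (i in seq_len(nSub))
      cmRows[[length(cmRows) + 1L]] <-
        data.frame(ref = subRefs[i], match = partner[i],
                   stringsAsFactors = FALSE)
    conceptGraph(do.call(rbind, unname(conceptRows)),
                 broader = do.call(rbind, broaderRows),
                 closeMatch = do.call(rbind, cmRows))
  })
}

#' Generate nested custom concept collections
#'
#' Adds `nCollections` collections over the graph's ICD codes; later
#' collections may nest earlier ones (never the converse), so the
#' collection-reference graph is acyclic by construction with nesting depth
#' bounded by `collectionNestingDepth`.
#'
#' @param spec a [fixtureSpec()].
#' @param graph the [ConceptGraph-class] to extend.
#' @return the graph with collections attached.
#' @export
genCollections <- function(spec, graph) {
  stopifnot(inherits(spec, "fixtureSpec"), is(graph, "ConceptGraph"))
  withSeed(subSeed(spec, 2L), {
    icd <- concepts(graph)$ref[concepts(graph)$scheme == "icd"]
    colls <- list()
    nestDepth <- integer(0)
    for (i in seq_len(spec$nCollections)) {
      nm <- sprintf("cc:condition%03d", i)
      k <- sample(2:5, 1L)
      members <- sample(icd, min(k, length(icd)))
      nestable <- names(colls)[nestDepth < spec$collectionNestingDepth]
      d <- 1L
      if (length(nestable) && stats::runif(1) < 0.4) {
        nest <- if (length(nestable) == 1L) nestable else sample(nestable, 1L)
        members <- c(members, nest)
        d <- nestDepth[[nest]] + 1L
      }
      colls[[nm]] <- members
      nestDepth[[nm]] <- d
    }
    g <- graph
    g@collections <- c(collections(graph), colls)
    validObject(g)
    g
  })
}

#' Generate a synthetic rule base over a graph
#'
#' Emits `nRules` positive boolean rules over existing codes, emulating the
#' shape of a curated drug indication/contraindication base: every premise
#' resolves against the graph, each rule's root is an operator node whose
#' internal nodes are OR with probability `orDensity` (AND otherwise),
#' indication premises are disease codes (ICD or collections), and
#' contraindication premises (a `contraindicationFraction` of the base) mix
#' disease and drug codes to encode drug--disease and drug--drug
#' interactions. Demographics are `any` for most rules and a random proper
#' subset otherwise.
#'
#' @param spec a [fixtureSpec()].
#' @param graph a non-empty [ConceptGraph-class].
#' @return a [RuleBase-class].
#' @export
genRulebase <- function(spec, graph) {
  stopifnot(inherits(spec, "fixtureSpec"), is(graph, "ConceptGraph"))
  cn <- concepts(graph)
  if (!nrow(cn)) validationStop("cannot generate rules over an empty graph")
  icd <- cn$ref[cn$scheme == "icd"]
  drugs <- cn$ref[cn$scheme %in% c("atc", "sub")]
  subs <- cn$ref[cn$scheme == "sub"]
  if (!length(subs)) validationStop("graph has no sub: substances for rule heads")
  ccs <- names(collections(graph))
  withSeed(subSeed(spec, 3L), {
    rules <- vector("list", spec$nRules)
    for (i in seq_len(spec$nRules)) {
      contra <- stats::runif(1) < spec$contraindicationFraction
      pool <- if (contra && length(drugs) && stats::runif(1) < 0.5)
        c(icd, drugs) else c(icd, ccs)
      genNode <- function(depth) {
        if (depth >= 3L || stats::runif(1) < 0.45) {
          return(list(kind = "atom",
                      ref = if (length(pool) == 1L) pool else sample(pool, 1L)))
        }
        kind <- if (stats::runif(1) < spec$orDensity) "or" else "and"
        nch <- sample(2:3, 1L)
        list(kind = kind, children = lapply(seq_len(nch),
                                            function(j) genNode(depth + 1L)))
      }
      ## root is always an operator so every rule exercises the logic
      rootKind <- if (stats::runif(1) < spec$orDensity) "or" else "and"
      expr <- list(kind = rootKind,
                   children = lapply(1:2, function(j) genNode(2L)))
      age <- if (stats::runif(1) < 0.7) "any" else
        sample(setdiff(RXR_AGE_GROUPS, "any"), sample(1:2, 1L))
      sex <- if (stats::runif(1) < 0.8) "any" else
        sample(setdiff(RXR_SEX_GROUPS, "any"), 1L)
      rules[[i]] <- new("MedicalRule",
        ruleId = sprintf("R%04d", i),
        substance = if (length(subs) == 1L) subs else sample(subs, 1L),
        polarity = if (contra) "contraindication" else "indication",
        expr = expr, ageGroups = age, sexGroups = sex)
    }
    ruleBase(rules, version = paste0("synthetic-", spec$seed))
  })
}

#' Generate synthetic patients for a graph
#'
#' @param spec a [fixtureSpec()].
#' @param graph a [ConceptGraph-class].
#' @return list of [Patient-class] objects with asserted ICD/ATC terms and
#'   concrete demographic groups.
#' @export
genPatients <- function(spec, graph) {
  stopifnot(inherits(spec, "fixtureSpec"), is(graph, "ConceptGraph"))
  cn <- concepts(graph)
  pool <- cn$ref[cn$scheme %in% c("icd", "atc")]
  withSeed(subSeed(spec, 4L), {
    lapply(seq_len(spec$nPatients), function(i) {
      k <- sample(spec$termsPerPatient[1]:spec$termsPerPatient[2], 1L)
      patient(sprintf("P%03d", i),
              sample(pool, min(k, length(pool))),
              ageGroup = sample(setdiff(RXR_AGE_GROUPS, "any"), 1L),
              sexGroup = sample(setdiff(RXR_SEX_GROUPS, "any"), 1L))
    })
  })
}

#' Generate a complete fixture bundle on disk
#'
#' Writes `terminology.tsv`, `collections.txt`, `rules.txt` and
#' `patients.json` for a spec into `dir`. Identical specs produce
#' byte-identical files.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return named list of the four file paths, invisibly.
#' @export
genFixtureBundle <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- genTerminology(spec)
  g <- genCollections(spec, g)
  rb <- genRulebase(spec, g)
  ps <- genPatients(spec, g)
  paths <- list(terminology = file.path(dir, "terminology.tsv"),
                collections = file.path(dir, "collections.txt"),
                rules = file.path(dir, "rules.txt"),
                patients = file.path(dir, "patients.json"))
  writeTerminology(g, paths$terminology)
  writeCollections(g, paths$collections)
  writeRuleBase(rb, paths$rules)
  jsonlite::write_json(
    lapply(ps, function(p) list(id = p@id, data = p@data,
                                age_group = p@ageGroup,
                                sex_group = p@sexGroup)),
    paths$patients, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Bundled worked-example fixtures
#'
#' Ready-made fixture bundles shipped with the package (plain-text files under
#' `inst/extdata/fixtures/`), packaging the canonical worked examples every
#' module is demonstrated and tested on:
#'
#' * `"d696_enrichment"` -- a four-level ICD-10 blood-disease fragment
#'   (D50-D89 > D65-D69 > D69 > D69.6) with the bone-marrow-deficiency
#'   collection listing D69.6 among its members, plus a thrombocytopenia
#'   patient; enrichment of `icd:D69.6` infers exactly
#'   `{icd:D69, icd:D65-D69, icd:D50-D89, cc:deficiency-bone-marrow}`.
#' * `"lisuride"` -- the lisuride indication rule
#'   `lisuride = icd:E22.0 | (icd:E22.1 & (icd:N91.0 | icd:N97)),
#'   ageGroup=adult or elder` with the ICD codes it premises; OR-elimination
#'   yields 3 conjunctive rules.
#' * `"cardiac_collections"` -- the cardiac-rhythm-abnormalities /
#'   bradycardia / tachycardia nested collection definitions.
#' * `"use_case_patient"` -- an elder male with atrial fibrillation (I48.2),
#'   vertigo (H81.49), hypertension (I10), diabetes (E11.9) and newly
#'   diagnosed pyelonephritis (N11.0), taking clopidogrel, cinnarizine,
#'   candesartan, amlodipine, metformin and sitagliptin (ATC-coded), with a
#'   small *synthetic* rule base and one evaluation case around the scenario.
#'
#' @param name one of the bundle names above.
#' @return named list of file paths (`terminology`, `collections`, `rules`,
#'   `patient`, `cases` -- entries present only where the bundle ships that
#'   file).
#' @examples
#' fx <- bundledFixture("d696_enrichment")
#' g <- readCollections(fx$collections, readTerminology(fx$terminology))
#' enrichPatient(readPatient(fx$patient), g)
#' @export
bundledFixture <- function(name = c("d696_enrichment", "lisuride",
                                    "cardiac_collections",
                                    "use_case_patient")) {
  name <- match.arg(name)
  dir <- system.file("extdata", "fixtures", name, package = "RxReasoner",
                     mustWork = TRUE)
  files <- c(terminology = "terminology.tsv", collections = "collections.txt",
             rules = "rules.txt", patient = "patient.json",
             cases = "cases.json")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  as.list(paths[file.exists(paths)])
}

#' Measure the OR share of a rule base's operator nodes
#'
#' The fraction of internal (and/or) nodes across all premise expressions
#' that are ORs -- the statistic the generator's `orDensity` setting targets.
#'
#' @param rb a [RuleBase-class].
#' @return numeric in `[0, 1]` (NaN for a base with no operator nodes).
#' @export
orShare <- function(rb) {
  stopifnot(is(rb, "RuleBase"))
  counts <- c(or = 0, internal = 0)
  rec <- function(node) {
    if (node$kind == "atom") return(invisible())
    counts["internal"] <<- counts["internal"] + 1
    if (node$kind == "or") counts["or"] <<- counts["or"] + 1
    lapply(node$children, rec)
    invisible()
  }
  for (r in rules(rb)) rec(r@expr)
  unname(counts["or"] / counts["internal"])
}
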
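---
title: "Two-layer terminology and rule reasoning for drug recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer terminology and rule reasoning for drug recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RxReasoner)
```

## The problem

Safe drug prescription requires checking a patient's coded record — diagnosed
diseases (ICD-10), current medication (ATC/UNII codes or substance names) —
against a curated knowledge base of indications, contraindications and
drug–drug/drug–disease interactions. Two difficulties dominate. First, codes
are hierarchical and redundant: a rule written against the purpura block
`icd:D65-D69` must also apply to a patient coded with the narrower
`icd:D69.6`, and a rule naming the substance *acetazolamide* must apply to a
patient whose record carries the equivalent ATC code `S01EC01`. Second, rule
bases are authored with disjunctions and groups ("any cardiac rhythm
abnormality"), while many production rule engines accept only conjunctive
rule bodies.

RxReasoner separates these concerns into two layers:

1. **Terminology inference** closes the patient record under the concept
   graph: broader-transitive ancestors, membership-triggered custom concept
   collections, and closeMatch equivalences. After this step the record is
   explicit — it contains every term any rule could legitimately match.
2. **Rule evaluation** is then pure, negation-free boolean matching of rule
   premises against the enriched term set, with demographic (age group, sex
   group) constraints, either directly on the and/or expression or after
   OR-elimination into conjunctive rules.

The final recommendation applies contraindication precedence: a substance
excluded by any fired contraindication never appears in the final list, no
matter how many indications fired (`final = canTake \ cannotTake`).
Interactions are binary; there is no severity weighting or fuzzy matching —
that is a deliberate scope boundary, not an accident of implementation.

## The data model

The concept graph stores, per scheme (`icd`, `atc`, `unii`, `ictv`, `sub`,
`cc`), plain concepts with labels, *direct* broader edges (a DAG; multiple
parents allowed), symmetric closeMatch pairs, and named custom concept
collections — ordered unions of codes and/or other collections. Only direct
hierarchy edges are stored; transitive closure is computed at inference
time. Hierarchy comes from an explicit parent column in the terminology TSV,
never from parsing code syntax, which keeps the loader agnostic to any one
coding system's conventions. The `pnc-cc:` spelling sometimes seen for
custom-collection references is normalised to the single canonical `cc:`
prefix on input.

Custom concepts (`cc:` singletons such as a bespoke "Narcolepsy" code) are
ordinary concepts and may carry parents; whether such concepts should
participate in the hierarchy is not settled by the source material for the
rule dialect, so the loader permits but does not require it.

```{r}
fx <- bundledFixture("cardiac_collections")
g <- readCollections(fx$collections, readTerminology(fx$terminology))
resolveCollection("cc:cardiac-rhythm-abnormalities", g)
```

Collection resolution flattens nested definitions recursively, merges
duplicates, and rejects cycles. It is idempotent and independent of member
order; the test suite checks it against a brute-force recursive expansion on
randomly nested systems.

## Enrichment semantics

Enrichment is a least fixpoint under three generators applied to the held
term set until nothing new appears, in a fixed order used only for
provenance tie-breaking (`ancestor` → `collection` → `equivalence`):

* every broader-transitive ancestor of a held term;
* every collection whose *resolved* set intersects the held terms, added by
  name;
* every closeMatch partner of a held term (chains close through iteration).

Three properties are deliberate:

* **Collections are never expanded downward.** Inferring membership of
  `cc:deficiency-bone-marrow` from `icd:D69.6` is sound; asserting the
  collection's *other* members (diseases the patient does not have) would
  not be. Closure only ever adds generalisations.
* **The trigger uses resolved member sets, not collection names.** A record
  asserting a collection name directly does not trigger enclosing
  collections, because enclosure is defined through member codes. This is a
  documented limitation; in practice patient records carry codes, not
  collection names.
* **Equivalence is bidirectional and transitive**: substance, ATC and UNII
  identifiers for the same ingredient are interchangeable wherever one of
  them is held.

Enrichment is monotone and idempotent, and the implementation (indexed BFS
plus pre-resolved collections) is verified against a naive
generate-until-no-change oracle on random graphs in every test run.

```{r}
fx <- bundledFixture("d696_enrichment")
g <- readCollections(fx$collections, readTerminology(fx$terminology))
ep <- enrichPatient(readPatient(fx$patient), g)
termProvenance(ep)
```

Age groups are fixed to `child`/`adult`/`elder`/`any` (with `any` matching
everything): rule authoring in this domain distinguishes adult and elderly
dosing populations, and `child` is the minimal complement. Sex groups are
`male`/`female`/`any`.

## The rule language and OR-elimination

Rules are one-per-line text: `[!]substance = expr`, with `&` binding tighter
than `|`, parentheses overriding, optional `ageGroup=`/`sexGroup=` clauses,
and a leading `!` marking a contraindication. There is no negation operator
in premises — everything downstream (monotonicity, selection soundness)
relies on that. The grammar is closed: clinical variables beyond age and sex
group (weight, creatinine clearance, ...) are out of scope for this dialect.

Drug–drug interactions are written as explicit contraindication pairs
(`!a = ...b...` and `!b = ...a...`); symmetry is not auto-generated, so the
rule base says exactly what its authors wrote.

`expandRule()` distributes AND over OR into a disjunction of conjunctions —
one conjunctive rule per disjunct, premises deduplicated, identical
conjuncts merged, deterministic left-to-right order, with a configurable
conjunct cap (default 10,000) guarding pathological blow-up:

```{r}
r <- parseRule(
  "lisuride = icd:E22.0 | (icd:E22.1 & (icd:N91.0 | icd:N97)), ageGroup=adult or elder")
expandRule(r)$premises
```

Because merging and deduplication are logically lossless, the disjunction of
the conjuncts is truth-table equivalent to the original expression; the
acceptance suite verifies this exhaustively (all `2^k` assignments, `k <= 8`
atoms) over 500 random expressions.

## Two-phase selection and the two strategies

Evaluating every expanded rule against every patient is wasteful. Selection
runs in two phases: phase 1 keeps rules whose demographic constraints are
compatible with the patient; phase 2, on the expanded conjuncts, keeps those
sharing at least one term with the enriched record — plain string matching,
since inference already materialised everything matchable. Firing then
requires *all* premises (and re-checks demographics, so selection is a pure
optimisation). For negation-free rules the two-phase funnel is provably
sound: a conjunct that fires must share every premise with the record, hence
at least one. The suite confirms exact recommendation equality with and
without selection over 200 random patients × 3 rule bases of 500–2,000
rules.

Two evaluation strategies exist because real rule engines differ: engines
without disjunction need the expanded route (selection + conjunct firing),
engines with OR in the body can evaluate the original expression directly
with no pre-selection. `recommend(..., strategy = "expanded")` and
`strategy = "direct"` implement both and must — and are continuously tested
to — return identical `canTake`/`cannotTake`/`final` sets.

```{r}
fx <- bundledFixture("use_case_patient")
g <- readCollections(fx$collections, readTerminology(fx$terminology))
rb <- readRuleBase(fx$rules)
rs <- recommend(readPatient(fx$patient), rb, g)
rs
queryRecommendations(rs)
```

Output sets are sorted lexicographically and fired rules ordered by rule id
then conjunct index, so identical inputs serialize byte-identically.

## Quality evaluation statistics

`analyzeCase()` mirrors a retrospective chart review: given a case (history,
new diagnoses, actually-prescribed drugs) it recommends for the full record
and reports per-case counts. Two definitional choices are interpretations
and are stated here prominently because chart-review summaries rarely
operationalise them:

* *Interaction vs contraindication*: an **interaction** is any fired
  contraindication rule; a **contraindication** is a fired rule whose
  substance was actually prescribed. Fired rules are counted once per
  original rule, not per conjunct.
* *Drug–drug vs drug–disease*: a fired contraindication whose matched
  premises are all drug/substance terms (`atc`/`unii`/`sub`, or a `cc:`
  collection resolving entirely to such terms) counts as drug–drug; one
  with at least one disease-term premise (`icd`/`ictv`, or any other `cc:`)
  counts as drug–disease. Whether drug–disease "interactions" in such
  reviews also count indication mismatches is ambiguous; here they count
  contraindication firings only.

Prescriptions are often ATC-coded while recommendations are substances, so
the match count closes both sides under closeMatch equivalence before
intersecting. `aggregateCases()` reports means rounded half-up to 2
decimals and the match percentage `100 * matched / administered` rounded
half-up to 1 decimal (so totals of 51 matching out of 76 administered report
67.1); rounding is half away from zero because that is how the summary
tables this mirrors are conventionally printed.

## Synthetic fixtures: what they emulate and what they do not

The generators (`genTerminology()`, `genCollections()`, `genRulebase()`,
`genPatients()`) produce random forests per scheme (depth-bounded,
multi-root), a flat substance scheme with substance≡ATC closeMatch pairs,
acyclic nested collections over disease codes, and positive boolean rules
whose internal nodes are OR with probability `orDensity`, with a
`contraindicationFraction` of rules premising drug codes. Defaults (50
concepts per scheme, depth 4, 10 collections, 100 rules, `orDensity` 0.5,
`contraindicationFraction` 0.3, 20 patients with 2–6 asserted terms) are
chosen as a desk-scale sketch of a real deployment's shape — thousands-fold
smaller than a production terminology, but with the same structural features
(multi-parent chains, nesting, mixed-polarity rules). A single integer seed
drives one PRNG substream per generator, and the caller's RNG state is
restored, so identical specs yield byte-identical bundles.

What the generators do **not** emulate: epidemiological co-occurrence
between diseases and drugs, realistic code-frequency distributions, or the
editorial structure of a curated rule base. Passing property suites on this
material therefore demonstrates the *logic* (closure correctness, DNF
equivalence, selection soundness, precedence) — it says nothing about
clinical coverage or recommendation quality on real data, which require the
real terminologies and a validated rule base.

Problem sizes in the shipped test suite — 500 random rules for the
truth-table suite, 200 patients × 3 bases of 500–2,000 rules for the
selection/strategy suites, 100 graph/patient pairs (graphs ≤ 300 concepts)
for the enrichment oracle, 20 random graphs for SKOS round-trips — are the
package's chosen verification scale: large enough for the properties to be
exercised across diverse shapes, small enough to run routinely.

## Numerical and formatting choices

* Rounding of reported statistics: half away from zero at the printed
  precision, with a `1e-9` guard against binary representation of exact
  ties.
* Degenerate inputs: empty rule bases yield empty recommendation sets; a
  root concept has no ancestors; an empty graph serializes to a
  prefix-only Turtle document and reads back empty. Duplicate codes, missing
  parents, hierarchy cycles, collection cycles and unresolvable patient
  terms are hard errors; dangling closeMatch targets are warnings (they can
  legitimately point outside a partial extract, and equivalence closure can
  still use them), whereas dangling collection members are errors because
  collections feed rule premises.
* Ties and ordering: everything user-visible is sorted (term sets
  lexicographically, fired rules by id then conjunct), making outputs
  diffable and runs reproducible.
* SKOS dialect: exactly four properties (`skos:prefLabel`,
  `skos:broaderTransitive`, `skos:closeMatch`, `skos:member`) plus
  `skos:Concept`/`skos:ConceptScheme`/`skos:Collection` typing, under the
  framework prefix `rxr:`. Only direct broader edges are serialized —
  transitivity is the reasoner's job, and emitting closures would bloat the
  document quadratically. Unknown properties on read are warn-and-skip so
  documents enriched by other tools still load.

## Known limitations

* No negation, severity weights, dosage fields or probabilistic semantics in
  the rule language.
* Collection triggering via resolved codes only (see above).
* The shipped fixtures' rule content is synthetic and illustrative; the
  package ships no real ICD-10/ATC/UNII/ICTV content and no clinical rule
  base.
* SPARQL is out of scope: querying is a structured API
  (`queryRecommendations()`) plus Turtle export for external engines.
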
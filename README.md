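# RxReasoner

Terminology-graph reasoning over drug indication and contraindication rules —
a desk-scale clinical decision-support engine for pharmacologists,
terminology engineers and CDS researchers who want the full reasoning
pipeline (coded record → enriched record → rule matching → precedence-filtered
recommendation) as inspectable, testable R objects rather than a black-box
service.

## The model

Patient records are sets of namespaced term references over standard
terminologies — ICD-10 diseases, ATC/UNII drug codes, substance names, virus
taxa — plus demographic groups. Reasoning runs in two layers:

**Layer 1 — terminology inference.** The concept graph stores SKOS-style
structure: direct `broaderTransitive` hierarchy edges, symmetric `closeMatch`
equivalences (substance ≡ ATC code), and custom concept collections
(expert-defined unions such as
`cardiac-rhythm-abnormalities = cc:bradycardia | icd:R00 | cc:tachycardia | icd:O68.0 | icd:O68.2`).
Enrichment closes a record under three generators to a least fixpoint:

- ancestors: `t ∈ record ∧ t ⊑* t'  ⟹  t' ∈ record`
- collections: `resolve(C) ∩ record ≠ ∅  ⟹  C ∈ record`
- equivalence: `t ∈ record ∧ t ≈ t'  ⟹  t' ∈ record`

**Layer 2 — rule evaluation.** Rules are negation-free boolean expressions
over term refs with age/sex-group constraints, one per substance and
polarity, e.g.

```
lisuride = icd:E22.0 | (icd:E22.1 & (icd:N91.0 | icd:N97)), ageGroup=adult or elder
!ibuprofen = cc:antithrombotic-agents
```

A rule can be evaluated directly, or OR-eliminated into conjunctive rules
(DNF: the lisuride rule expands to premise sets `{E22.0}`, `{E22.1, N91.0}`,
`{E22.1, N97}`) for engines that forbid disjunction — both strategies return
identical results. A two-phase selection funnel (demographic filter Â, then
premise-term overlap R ⊆ Â) cuts the rules actually evaluated without
changing any recommendation, which is provable because premises are positive
only. Fired indications populate `canTake`, fired contraindications
`cannotTake`, and contraindication precedence gives the final list
`final = canTake ∖ cannotTake`.

The package also ships the terminology TSV / collection / rule-file /
patient-JSON dialects, SKOS Turtle import/export, deterministic synthetic
fixture generators, cohort quality-evaluation statistics, and a CLI
(`exec/rxreasoner`).

## Worked example

An elder man with chronic atrial fibrillation (on clopidogrel), vertigo (on
cinnarizine), hypertension (on candesartan and amlodipine) and type-2
diabetes (on metformin and sitagliptin) is newly diagnosed with
pyelonephritis (`icd:N11.0`):

```r
library(RxReasoner)
fx <- bundledFixture("use_case_patient")
g  <- readCollections(fx$collections, readTerminology(fx$terminology))
rb <- readRuleBase(fx$rules)
p  <- readPatient(fx$patient)

enrichPatient(p, g)
#> EnrichedPatient use-case-elder - 11 asserted + 17 inferred term(s)

rs <- recommend(p, rb, g)
rs
#> RecommendationSet: 3 canTake, 2 cannotTake, 2 final recommendation(s); 6 fired rule conjunct(s)
#>   selection: 6 total -> 6 demographic candidates -> 6 premise-matched (expanded strategy)

queryRecommendations(rs)
#>           substance         polarity in_final rule_ids
#> 1 sub:ciprofloxacin       indication     TRUE    R0001
#> 2    sub:fosfomycin       indication     TRUE    R0002
#> 3     sub:ibuprofen contraindication    FALSE    R0004
#> 4     sub:ibuprofen       indication    FALSE    R0003
#> 5     sub:metformin contraindication    FALSE    R0005
```

Reading the output: enrichment added 17 implied terms (ATC class parents,
ICD block parents, the substance equivalents of the six ATC-coded drugs, and
the `cc:antithrombotic-agents` collection triggered by clopidogrel). Three
indications fired for the new diagnosis (ciprofloxacin, fosfomycin,
ibuprofen), but ibuprofen is also hit by a drug–drug contraindication
against the antithrombotic the patient already takes, and metformin by a
drug–disease contraindication — so the final recommendation is
**ciprofloxacin** and **fosfomycin** only. (The demo rule base is synthetic
and illustrative, not clinical advice.)

The same run from the shell:

```sh
Rscript exec/rxreasoner recommend \
  --terminology inst/extdata/fixtures/use_case_patient/terminology.tsv \
  --collections inst/extdata/fixtures/use_case_patient/collections.txt \
  --rules inst/extdata/fixtures/use_case_patient/rules.txt \
  --patient inst/extdata/fixtures/use_case_patient/patient.json
```

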
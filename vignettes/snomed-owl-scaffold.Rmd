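---
title: "From release files to a formally consistent ontology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From release files to a formally consistent ontology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctforge)
```

# The problem

SNOMED CT is distributed as tab-separated release files (RF2): a Concept
table, a Description table, and a Relationship table. The content is
logic-shaped — concepts are partially defined by IS_A parents and by
attribute–value pairs, and clinicians compose *post-coordinated expressions*
in a compositional grammar — but the distribution itself is not a logic.
`sctforge` turns this content into a formally consistent OWL 2 artifact:

1. **rf2 store** — read, validate, index, and write snapshot tables;
2. **fixtures** — generate miniature, self-contained snapshots (no licensed
   release is ever required);
3. **compositional grammar** — parse and serialize expressions;
4. **description logic core** — translate expressions into a lightweight
   EL++ subset with role groups, with a finite-model semantics;
5. **reasoner** — classify, decide subsumption/equivalence, search for
   bounded counter-models, and eliminate redundant grouped restrictions;
6. **ontology builder** — the OGMS-aligned upper-level scaffold, reified
   record schema, concept-model validation;
7. **emitter** — deterministic OWL 2 functional and Manchester syntax;
8. **metrics** — ontology structure and relationship-group statistics.

# The logic

The supported constructs are the EL++ subset actually used by the
terminology: `⊤`, `⊥`, concept names, conjunction, existential restriction,
general class inclusions and equivalences, role inclusions, domain and
range restrictions, and pairwise disjointness. Negation, disjunction,
universal quantification as a class constructor, and inverse roles do not
exist at the type level — constructing them is impossible, not merely
unchecked. Semantics are the standard set semantics over finite
interpretations (`dl_interpretation()`, `extension()`, `is_model()`), which
double as a brute-force oracle in the test suite.

## Role groups

Attribute groups ("a morphology with its specific body site") are written
with braces in the grammar and modeled as `dl_group()`. Internally a group
desugars to an existential over a single reserved role `RG` with the member
conjunction as filler, so one calculus decides grouped and ungrouped
subsumption alike: one group is subsumed by another exactly when the member
conjunctions subsume.

One further commitment is needed. The published redundancy identity

```
∃R.C ⊓ {∃R.C ⊓ ∃S.D}  =  {∃R.C ⊓ ∃S.D}
```

treats an ungrouped restriction as *entailed* by its grouped duplicate,
which is false under a bare `∃RG` reading. This package therefore gives the
group role composition semantics — `RG ∘ R ⊑ R`, "an attribute stated
inside a group still holds of the source concept" — applied uniformly in
the classifier, the naive oracle, and both model builders. Under this
reading all three published redundancy identities are genuine equivalences,
which the test suite verifies with the reasoner itself.

## Classification

`classify()` normalizes axioms to the standard completion normal forms
(fresh names for complex subexpressions; left-hand complexes entail their
atom, right-hand existential filler atoms entail their complex) and
saturates subsumer sets and role-successor pairs under the completion
rules, with the role hierarchy closed on edge insertion, ranges applied at
existential introduction, and unsatisfiability (`⊥`) propagated backwards
over edges. This is polynomial in the size of the terminology.
`naive_closure()` computes the same relation by exhaustive unindexed rule
application with its own small normalizer — deliberately independent code,
kept as an oracle. `subsumes(a, b)` internalizes both expressions as fresh
defined names and reads the answer off the saturation.

`find_countermodel()` is the third, semantic route: it builds the least
model containing a witness of `a` (one individual per distinct existential
filler, at most `max_domain` individuals; surplus individuals fold onto the
last node, which can only make the test conservative) and closes it under
the axioms by monotone repair. If the witness fails `b`, that finite
interpretation *is* the refutation, and it is checked with `is_model()`
before being returned.

## Qualification

Refining with a qualifier normally specializes: *periodic fever accompanied
by chills* is subsumed by *fever with chills*. Context-setting attributes
break this — a finding qualified as known-absent is not an instance of the
finding. `qualifier_policy()` carries the list of context attributes
(default: the single placeholder 408729009, since the context hierarchies
are out of scope); when the left expression carries one, its focus-concept
conjuncts are excluded from the premises, so subsumption by the focus
concept fails while attribute-mediated entailments survive.

# The grammar

`parse_cg()` accepts two dialects. The worked examples motivate the
`"paper"` dialect: attribute groups may be written with plain parentheses
in item position (braces always work), and an attribute may omit `=`
between name and value — juxtaposition of two concept references in a
refinement context reads as name = value. The `"standard"` dialect requires
`=`, allows only braces for groups, and accepts `+` between focus concepts.
Parentheses immediately after `=` always open a nested expression (doubled
parentheses accepted); numeric concrete values carry `#`; terms (`|...|`)
are labels with no semantics. The canonical normal form (`cg_canonical()`,
`cg_normal_form()`) strips terms and sorts focus concepts, attributes, and
groups by their term-free serialization — *lexicographically on the
identifier strings*, which is what makes `"129249002, 7246002"` the normal
form of the needle-biopsy combination.

# The artifact

`build_scaffold()` constructs the fresh ontology: a `SNOMED CT component`
root with `SNOMED CT Concept` / `Description` / `Relationship` subclasses;
a label-only stub tree standing in for the OGMS/BFO upper level (the real
upper ontologies are not imported; every stub is marked synthetic in its
definition); the 8 object properties and 20 data properties of the reified
schema; a single pairwise-disjointness axiom over the 15 top-level
hierarchy classes; and label + textual-definition annotations on every
class and property. The 20 data properties partition the preserved RF2
fields: 5 for Concept, 8 for Description, 7 for Relationship.

The default mapping table resolves an arithmetic tension in its source
counts: 19 top-level hierarchies with 3 excluded leaves 16 modeled, yet the
published shares (82.35% / 11.77% / 5.88%) imply 14 + 2 + 1 = 17 mapped
entries. The table therefore has 20 rows — the 19 top-level concepts plus
the root concept, whose placement under `entity` is itself one of the 14
subsumption mappings — making "19 covered, 16 modeled, 14/17 subsumption"
simultaneously true. The exact upper-level target of each entry is
configuration, not doctrine; the shipped defaults are the package's own
choices (e.g. *clinical finding* under a disorder stub, *body structure*
under an anatomical-entity stub).

`reify()` pours a snapshot in: concept rows become classes `SCTO_<id>`
(subclass axioms per parent for primitive concepts; one equivalence over
parents plus reified restrictions for fully defined ones — the
`definitionStatusId` decides), IS_A rows become subclass axioms and never
individuals or object properties, and description/relationship rows become
individuals carrying every preserved record field. `materialize_groups()`
applies the grouping rule directly: distinct relationship individuals with
the same source and equal non-zero group number are linked by the symmetric
`Grouped_Relations` property (the published rule text omits the same-source
and non-zero conditions; without them every pair of group-1 rows across
unrelated concepts would link, which cannot be intended — the stored rule
record states the corrected conditions).

`expression_to_axioms()` renders a parsed expression over the reified
schema: each refinement becomes an `IsSourceOf some
(Relationship_destinationId some V and Relationship_typeId some A)` block;
in the `"reified"` pattern, group members are additionally chained with
`Grouped_Relations exactly 1` linkages. Concrete values become data
restrictions on an expression-local data property declared on demand (the
fixed 20-property schema has no slot for them).

Qualified cardinality and `only` exceed the lightweight profile the
artifact otherwise inhabits — the hand-written listings use them anyway.
Rather than guessing intent, `emit()` offers both: the `dl` profile emits
axioms as modeled; the `el_safe` profile replaces `exactly 1` linkages by
plain existentials and drops `only` restrictions with a logged warning.
Functional syntax is canonical (sorted declarations, then axioms; two
emissions of equal ontologies are byte-identical — golden-file testing
depends on it); Manchester is display-only.

# Synthetic data: what it emulates, and what it does not

`paper_fixture()` contains every concept, description, and relationship the
worked examples use, with printed hierarchy edges as printed and invented
edges (needed to give each concept a home under the right top-level
hierarchy) flagged `synthetic = TRUE` in a manifest. The grouped definition
of *tetralogy of Fallot* uses synthetic morphology/site concepts because
the source presents that structure only in figure form. `random_taxonomy()`
grows an acyclic IS_A DAG (each concept parents only among earlier ones),
sprinkles non-IS_A rows over synthetic attribute types, and bundles a
configurable fraction of them into shared groups; defaults (50 concepts,
3 attribute types, ≤3 parents, 30% grouped, 1 non-IS_A row per concept)
are sized like a small neighborhood of the real terminology.

What passing tests on these fixtures shows: the machinery is correct on
structures of this shape. What it does not show: behavior at full-release
scale (hundreds of thousands of concepts, multi-million-row relationship
tables), nor the content statistics of any licensed release — those numbers
depend on the release itself and are computable by `rf2_group_stats()` on
whatever snapshot is supplied.

# Numerical and procedural choices

* Identifiers stay strings end-to-end (they overflow 53-bit doubles, and
  the normal form needs lexicographic order); `relationshipGroup` is the
  one integer column.
* All randomness flows through explicit seeds (`withr::with_seed`);
  generators, the model search, and emission are fully deterministic.
* Rewrite rules apply innermost-first — within groups (3), then across
  groups (2), then ungrouped-vs-group (1) — and re-canonicalize to
  fixpoint. Each rule removes only conjuncts entailed by what remains, so
  the fixpoint does not depend on the order; ties between mutually covering
  members/groups are broken toward the canonically smaller key.
* Counter-model search is bounded at 8 individuals (documented cost bound;
  the default 6 covers the expression depths the generators produce).
* Degenerate inputs: empty snapshots validate and reify to nothing; a
  snapshot with no non-IS_A rows has grouped share 0 with a warning; an
  empty rule table accepts everything; cyclic IS_A input is rejected with a
  named cycle.
* Test and oracle problem sizes — 100 random terminologies (25 names, 4
  roles) for classifier/oracle agreement, 200 expression pairs against the
  bounded model search, 200 grouped expressions for rewrite equivalence, 50
  repaired random models for soundness — are the package's chosen
  verification scale; the whole suite runs in under two minutes.

# Known limitations

* No concrete-domain reasoning: equal concrete values compare equal,
  nothing more.
* No ABox instance checking, no incremental reclassification, no reference
  sets, no Full/Delta release history, no temporal interpretation of
  `effectiveTime`.
* The upper-level stubs are labels with a plausible tree, not the real
  OGMS/BFO axiomatizations; alignment claims are only as strong as the
  shipped mapping defaults, which are configuration.
* Classes double as property-assertion subjects in the reified ABox
  (punning); a strict OWL 2 DL checker would want declared individuals for
  concept records as well.
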
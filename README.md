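# sctforge

Turn SNOMED CT content into a formally consistent OWL 2 ontology.

SNOMED CT ships as tab-separated release files (RF2) whose content is
logic-shaped but not a logic: concepts are partially defined by IS_A
parents and attribute–value pairs, and clinical meanings not present as a
single concept are composed as *post-coordinated expressions* in a
compositional grammar. `sctforge` is for terminologists and ontology
engineers who want that content as a real ontology: it parses the
compositional grammar, translates expressions into a lightweight EL++
description logic with role groups, classifies terminologies by
completion-rule saturation (with a naive fixpoint oracle and a bounded
finite-model search as independent cross-checks), eliminates redundant
grouped restrictions, and emits an upper-level ontology scaffold aligned
with OGMS/BFO — the reified Concept/Description/Relationship schema with
its 8 object and 20 data properties — in deterministic OWL 2 functional or
Manchester syntax.

The logic at the core is the EL++ subset the terminology actually uses —
⊤, ⊥, concept names, C ⊓ D, ∃R.C, GCIs C ⊑ D and C ≡ D, role inclusions
R ⊑ S, domain/range restrictions, and disjointness C ⊓ D ⊑ ⊥ — extended
with role groups `{∃R.C ⊓ ∃S.D}`, desugared internally to an existential
over a reserved group role with composition semantics (RG ∘ R ⊑ R), so
grouped and ungrouped restrictions are mutually comparable and subsumption
stays polynomial. No licensed release is required anywhere: a fixture
module generates a miniature snapshot containing every concept used by the
worked examples, plus seeded random taxonomies.

## Worked example

```r
library(sctforge)

snap <- paper_fixture()        # miniature RF2 snapshot, built in code
glance(snap)
#> # A tibble: 1 × 6
#>   concepts descriptions relationships active_is_a non_is_a grouped
#>      <int>        <int>         <int>       <int>    <int>   <int>
#> 1       73           73            88          74       14      12

# parse a refinement and print its term-free normal form
cg_normal_form("125605004 |Fracture of bone|: 363698007 |Finding site| = 181940002 |Radius|")
#> [1] "125605004: 363698007 = 181940002"

# qualification specializes: periodic fever accompanied by chills
# is subsumed by fever with chills
tb <- snapshot_tbox(snap)
a  <- cg_to_dl(parse_cg("274640006 |fever with chills|: 246456000 |episodicity| = 81591007 |periodic|"))$expr
subsumes(tb, a, "274640006")
#> [1] TRUE

# build the artifact: scaffold + reified records + grouping rule
ont <- materialize_groups(reify(snap, build_scaffold()))
declaration_census(emit(ont))
#> # A tibble: 1 × 7
#>   classes object_properties data_properties individuals class_axioms
#>     <int>             <int>           <int>       <int>        <int>
#> 1      98                 8              20          87          114

mapping_summary()
#> # A tibble: 1 × 6
#>   covered_top_level modeled mapped_entries subsumption_pct equivalence_pct
#>               <int>   <int>          <int>           <dbl>           <dbl>
#> 1                19      16             17            82.4            11.8
```

Reading the numbers: the fixture's 73 concepts reify to 98 classes (the
scaffold adds the component schema and the upper-level stubs), always with
exactly 8 object and 20 data properties; of the 14 active non-IS_A rows,
12 sit in relationship groups, which `materialize_groups()` links pairwise
with the symmetric `Grouped_Relations` property. The default mapping
covers all 19 top-level hierarchies, models 16 of them (three have no
upper-level home), and 14 of its 17 mapped entries are subsumptions
(82.35%).

A command-line front end wraps the same functions:

```sh
Rscript exec/forge fixtures paper --out fx
Rscript exec/forge normal-form "7246002 |Kidney biopsy|, 129249002"   # 129249002, 7246002
Rscript exec/forge subsumes --rf2 fx "274640006: 246456000 = 81591007" "274640006"
Rscript exec/forge emit --rf2 fx --syntax ofn --profile el_safe
Rscript exec/forge metrics --rf2 fx
```

See the vignette (`vignettes/snomed-owl-scaffold.Rmd`) for the model, the
role-group semantics, the normalization and completion rules, and the
design decisions.

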
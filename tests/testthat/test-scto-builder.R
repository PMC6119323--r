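scaffold <- build_scaffold()

test_that("a fresh scaffold has the published schema shape", {
  expect_setequal(scaffold$object_properties$name,
                  c("Has_description", "IsDescriptionOf",
                    "Relationship_destinationId", "Relationship_sourceId",
                    "Relationship_typeId", "IsSourceOf", "IsDestinationOf",
                    "Grouped_Relations"))
  expect_equal(nrow(scaffold$object_properties), 8)
  expect_equal(nrow(scaffold$data_properties), 20)
  disjoints <- purrr::keep(scaffold$class_axioms, ~ .x$kind == "disjoint")
  expect_length(disjoints, 1)
  expect_length(disjoints[[1]]$members, 15)
  # the component root has exactly the three record subclasses
  edges <- sctforge:::ontology_edges(scaffold)
  children <- edges$child[edges$parent == "SCTO_Component"]
  expect_setequal(children,
                  c("SCTO_138875005", "SCTO_Description", "SCTO_Relationship"))
  # excluded hierarchies produce no class
  expect_false(any(c("SCTO_48176007", "SCTO_243796009", "SCTO_370115009")
                   %in% scaffold$classes$iri))
  # the linkage concept hangs under the root concept only
  lk <- edges$parent[edges$child == "SCTO_106237007"]
  expect_identical(lk, "SCTO_138875005")
})

test_that("mapping validation enforces the published counts", {
  m <- default_mapping()
  expect_silent(validate_mapping(m))
  expect_error(validate_mapping(m[-2, ]), "19 top-level")
  bad <- m
  bad$kind[bad$sct_id == "410607006"] <- "subsumption"
  expect_error(validate_mapping(bad), "14 subsumption")
  s <- mapping_summary(m)
  expect_equal(s$covered_top_level, 19)
  expect_equal(s$modeled, 16)
  expect_equal(round(s$subsumption_pct, 2), 82.35)
  expect_equal(round(s$equivalence_pct, 2), 11.76)
  expect_equal(round(s$no_equivalence_pct, 2), 5.88)
})

snap <- paper_fixture()
reified <- reify(snap, scaffold)

test_that("IS_A rows become subclass axioms and never individuals", {
  ax <- purrr::keep(reified$class_axioms,
                    ~ .x$kind == "subclass" && identical(.x$subject, "SCTO_73211009"))
  parents <- purrr::map_chr(ax, ~ .x$expr$iri)
  expect_setequal(parents, c("SCTO_126877002", "SCTO_362969004"))
  # no relationship individual was created for any IS_A row
  isa_ids <- snap$relationships$id[snap$relationships$typeId == "116680003"]
  expect_false(any(paste0("rel_", isa_ids) %in% reified$individuals$id))
})

test_that("non-IS_A rows are reified with their record fields", {
  expect_true("rel_2034997023" %in% reified$individuals$id)
  obj <- dplyr::filter(reified$assertions, subject == "rel_2034997023")
  expect_identical(obj$object[obj$property == "Relationship_sourceId"],
                   "SCTO_56265001")
  expect_identical(obj$object[obj$property == "Relationship_typeId"],
                   "SCTO_363698007")
  expect_identical(obj$object[obj$property == "Relationship_destinationId"],
                   "SCTO_80891009")
  dat <- dplyr::filter(reified$data_assertions, subject == "rel_2034997023")
  expect_identical(dat$value[dat$property == "Relationship_relationshipGroup"],
                   "0")
  expect_identical(dat$value[dat$property == "Relationship_active"], "true")
})

test_that("descriptions are reified with their term text", {
  desc <- dplyr::filter(reified$data_assertions,
                        property == "Description_term",
                        value == "tetralogy of Fallot")
  expect_equal(nrow(desc), 1)
  link <- dplyr::filter(reified$assertions, property == "Has_description",
                        object == desc$subject)
  expect_identical(link$subject, "SCTO_86299006")
})

test_that("a fully defined concept receives one equivalence axiom", {
  ax <- purrr::keep(reified$class_axioms,
                    ~ identical(.x$subject, "SCTO_111613008"))
  expect_length(ax, 1)
  expect_identical(ax[[1]]$kind, "equivalent")
})

test_that("reify on an empty snapshot changes nothing", {
  expect_identical(emit(reify(rf2_snapshot(), scaffold)), emit(scaffold))
})

test_that("group materialization links exactly the shared non-zero groups", {
  ont <- materialize_groups(reified)
  # closed-skull: 2 groups of 2; tetralogy: 4 groups of 2 -> 6 pairs
  expect_equal(nrow(ont$grouped_relations), 6)
  expect_true(all(ont$grouped_relations$r1 < ont$grouped_relations$r2))
  # the ungrouped tetralogy variant contributes no pairs for group-0 rows
  ont0 <- materialize_groups(reify(paper_fixture(tetralogy_grouped = FALSE),
                                   scaffold))
  tet_ids <- paste0(
    "rel_", snap$relationships$id[snap$relationships$sourceId == "86299006"])
  expect_false(any(ont0$grouped_relations$r1 %in% tet_ids |
                     ont0$grouped_relations$r2 %in% tet_ids))
  expect_equal(nrow(ont0$grouped_relations), 2)  # the closed-skull groups stay
})

test_that("pair counts match the combinatorial formula on random fixtures", {
  for (seed in c(21, 22, 23)) {
    rsnap <- random_taxonomy(fixture_config(seed = seed, n_concepts = 40,
                                            grouped_fraction = 0.6,
                                            relationship_rate = 2))
    ont <- materialize_groups(reify(rsnap, build_scaffold()))
    rel <- dplyr::filter(rsnap$relationships, typeId != "116680003",
                         relationshipGroup > 0L)
    expected <- rel |>
      dplyr::count(sourceId, relationshipGroup) |>
      dplyr::summarise(pairs = sum(n * (n - 1) / 2)) |>
      dplyr::pull(pairs)
    expect_equal(nrow(ont$grouped_relations), expected)
  }
})

test_that("a single relationship in a group yields no pair", {
  s <- rf2_snapshot(
    concepts = tibble::tibble(id = c("1", "2", "3"),
                              effectiveTime = "20150731", active = "1",
                              moduleId = "900000000000207008",
                              definitionStatusId = "900000000000074008"),
    relationships = tibble::tibble(
      id = "10", effectiveTime = "20150731", active = "1",
      moduleId = "900000000000207008", sourceId = "1", destinationId = "2",
      relationshipGroup = 1L, typeId = "3",
      characteristicTypeId = "900000000000011006",
      modifierId = "900000000000451002"))
  ont <- materialize_groups(reify(s, build_scaffold()))
  expect_equal(nrow(ont$grouped_relations), 0)
})

test_that("the diabetes expression renders as a plain restriction axiom", {
  ex <- cg_examples()
  ont <- expression_to_axioms(parse_cg(ex[["ex1"]]), reified, "plain")
  ax <- purrr::keep(ont$class_axioms,
                    ~ identical(.x$subject, "SCTO_73211009") &&
                      .x$kind == "subclass" && .x$expr$variant == "and")
  expect_length(ax, 1)
  doc <- sctforge:::cexpr_functional(ax[[1]]$expr)
  expect_match(doc, ":SCTO_126877002")
  expect_match(doc, ":SCTO_362969004")
  expect_match(doc, "ObjectSomeValuesFrom\\(:IsSourceOf")
  expect_match(doc, ":SCTO_113331007")
  expect_match(doc, ":SCTO_363698007")
})

test_that("the reified pattern chains group members with cardinality linkages", {
  ex <- cg_examples()
  ont <- expression_to_axioms(parse_cg(ex[["ex5"]]), reified, "reified")
  ax <- purrr::keep(ont$class_axioms,
                    ~ identical(.x$subject, "SCTO_111613008") &&
                      .x$kind == "equivalent" && .x$expr$variant == "and")
  expect_length(ax, 1)
  doc <- sctforge:::cexpr_functional(ax[[1]]$expr)
  expect_equal(lengths(regmatches(doc, gregexpr("ObjectExactCardinality\\(1 :Grouped_Relations", doc))), 2)
  expect_match(doc, ":SCTO_450695007")
  expect_match(doc, ":SCTO_89546000")
  # a single focus concept with no refinement emits a bare axiom
  plain <- expression_to_axioms(parse_cg("=== 27658006"), reified, "plain",
                                label = "just amoxicillin")
  ax2 <- purrr::keep(plain$class_axioms,
                     ~ identical(.x$subject, "SCTO_EXP_just_amoxicillin"))
  expect_identical(ax2[[1]]$expr$variant, "ref")
  # unknown identifiers are refused
  expect_error(expression_to_axioms(parse_cg("99999999"), reified),
               "unknown class")
})

taxonomy <- taxonomy_index(snap)

test_that("concept-model validation accepts the printed finding-site use", {
  ex <- cg_examples()
  v <- scm_validate(parse_cg(ex[["radius_fracture"]]), default_scm_rules(),
                    taxonomy)
  expect_equal(nrow(v), 0)
  # heart disease with a heart-structure finding site, via the snapshot path
  v2 <- scm_validate(snap, default_scm_rules(), taxonomy)
  expect_equal(nrow(v2), 0)
})

test_that("a finding site pointing at an organism is a range violation", {
  v <- scm_validate("404684003: 363698007 = 9861002", default_scm_rules(),
                    taxonomy)
  expect_equal(nrow(v), 1)
  expect_identical(v$problem, "range")
  expect_identical(v$value, "9861002")
})

test_that("an attribute applied outside its domain hierarchy is flagged", {
  # finding site on a pharmaceutical product
  v <- scm_validate("27658006: 363698007 = 80891009", default_scm_rules(),
                    taxonomy)
  expect_equal(nrow(v), 1)
  expect_identical(v$problem, "domain")
})

test_that("an empty rule table accepts anything", {
  empty <- default_scm_rules()[0, ]
  v <- scm_validate(snap, empty, taxonomy)
  expect_equal(nrow(v), 0)
})

test_that("nested expression refinements are validated recursively", {
  ex <- cg_examples()
  v <- scm_validate(parse_cg(ex[["ex8"]]), default_scm_rules(), taxonomy)
  expect_equal(nrow(v), 0)
  # break the nested laterality value
  bad <- "87628006: 363698007 = (45653009, 272741003 = 9861002)"
  v2 <- scm_validate(bad, default_scm_rules(), taxonomy)
  expect_equal(nrow(v2), 1)
  expect_identical(v2$attribute, "272741003")
})
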
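test_that("hierarchy metrics are hand-countable on a 3-class chain", {
  ont <- sctforge:::empty_ontology()
  ont <- sctforge:::ont_add_class(ont, "root", "root", "d")
  ont <- sctforge:::ont_add_class(ont, "A", "A", "d")
  ont <- sctforge:::ont_add_class(ont, "B", "B", "d")
  ont <- sctforge:::ont_add_axiom(ont, sctforge:::owl_axiom(
    "subclass", subject = "A", expr = sctforge:::o_ref("root")))
  ont <- sctforge:::ont_add_axiom(ont, sctforge:::owl_axiom(
    "subclass", subject = "B", expr = sctforge:::o_ref("A")))
  m <- ontology_metrics(ont)
  expect_equal(m$max_depth, 2)
  expect_equal(m$max_parents, 1)
  expect_equal(m$single_child_classes, 2)
  expect_equal(m$max_children, 1)
  expect_equal(m$classes, 3)
  expect_equal(m$subclass_axioms, 2)
})

test_that("the fresh scaffold reports the published property counts", {
  m <- ontology_metrics(build_scaffold())
  expect_equal(m$object_properties, 8)
  expect_equal(m$data_properties, 20)
  expect_gt(m$max_depth, 2)
})

test_that("subclass axioms equal active IS_A rows plus scaffold axioms", {
  scaffold <- build_scaffold()
  scaffold_sub <- sum(purrr::map_chr(scaffold$class_axioms, "kind") ==
                        "subclass")
  for (seed in c(41, 42)) {
    snap <- random_taxonomy(fixture_config(seed = seed, n_concepts = 30))
    ont <- reify(snap, scaffold)
    isa <- sum(snap$relationships$typeId == "116680003" &
                 snap$relationships$active == "1")
    m <- ontology_metrics(ont)
    expect_equal(m$subclass_axioms, scaffold_sub + isa)
  }
})

test_that("metrics ignore the storage order of classes and axioms", {
  ont <- reify(paper_fixture(), build_scaffold())
  m1 <- ontology_metrics(ont)
  shuffled <- ont
  withr::with_seed(1, {
    shuffled$classes <- shuffled$classes[sample(nrow(shuffled$classes)), ]
    shuffled$class_axioms <- sample(shuffled$class_axioms)
  })
  m2 <- ontology_metrics(shuffled)
  expect_equal(m1, m2)
})

test_that("group statistics match a hand count and warn when degenerate", {
  snap <- paper_fixture()
  gs <- rf2_group_stats(snap)
  expect_equal(gs$n_non_isa, 14)
  expect_equal(gs$n_grouped, 12)
  expect_equal(gs$grouped_pct, 100 * 12 / 14)
  expect_equal(sum(gs$by_attribute$share_pct), 100)
  # one grouped of two non-IS_A rows -> 50%
  s <- rf2_snapshot(
    concepts = tibble::tibble(id = c("1", "2", "3"),
                              effectiveTime = "20150731", active = "1",
                              moduleId = "900000000000207008",
                              definitionStatusId = "900000000000074008"),
    relationships = tibble::tibble(
      id = c("10", "11"), effectiveTime = "20150731", active = "1",
      moduleId = "900000000000207008", sourceId = "1",
      destinationId = "2", relationshipGroup = c(1L, 0L), typeId = "3",
      characteristicTypeId = "900000000000011006",
      modifierId = "900000000000451002"))
  expect_equal(rf2_group_stats(s)$grouped_pct, 50)
  expect_warning(empty <- rf2_group_stats(rf2_snapshot()), "no active")
  expect_equal(empty$grouped_pct, 0)
})

test_that("the configured grouped fraction is recovered on large fixtures", {
  snap <- random_taxonomy(fixture_config(seed = 8, n_concepts = 400,
                                         grouped_fraction = 0.4,
                                         relationship_rate = 3))
  gs <- rf2_group_stats(snap)
  expect_gt(gs$n_non_isa, 1000)
  expect_lt(abs(gs$grouped_pct - 40), 5)
})

test_that("tidiers and plots expose the result objects", {
  snap <- paper_fixture()
  g <- glance(snap)
  expect_equal(g$concepts, nrow(snap$concepts))
  ont <- reify(snap, build_scaffold())
  expect_equal(nrow(tidy(ont)), length(ont$class_axioms))
  expect_s3_class(glance(ont), "metric_report")
  rel <- classify(snapshot_tbox(snap))
  expect_named(tidy(rel), c("sub", "super"))
  p1 <- ggplot2::autoplot(ontology_metrics(ont))
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(rf2_group_stats(snap))
  expect_s3_class(p2, "ggplot")
})
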
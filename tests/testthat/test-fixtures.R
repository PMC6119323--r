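test_that("the paper fixture is deterministic and validates", {
  a <- paper_fixture()
  b <- paper_fixture()
  expect_identical(a$concepts, b$concepts)
  expect_identical(a$relationships, b$relationships)
  expect_silent(validate_snapshot(a))
})

test_that("every SCTID used by the worked examples is present", {
  ids <- c("73211009", "126877002", "362969004", "363698007", "113331007",
           "7246002", "129249002", "125605004", "181940002", "71388002",
           "405815000", "122456005", "260686004", "129304002", "405813007",
           "15497006", "111613008", "451000119106", "371162008", "116676008",
           "450695007", "128319008", "20946005", "89546000", "27658006",
           "411116001", "385049006", "127489000", "372687004", "258684004",
           "274640006", "246456000", "81591007", "87628006", "246075003",
           "9861002", "45653009", "272741003", "7771000", "56265001",
           "80891009", "86299006", "246061005", "410662002", "116680003",
           "111115")
  snap <- paper_fixture()
  expect_true(all(ids %in% snap$concepts$id))
  fsn <- snap$descriptions$term[snap$descriptions$conceptId == "86299006"]
  expect_identical(fsn, "tetralogy of Fallot")
})

test_that("the fixture carries the printed relationship rows", {
  rel <- paper_fixture()$relationships
  heart <- dplyr::filter(rel, sourceId == "56265001", typeId == "363698007")
  expect_identical(heart$destinationId, "80891009")
  expect_identical(heart$relationshipGroup, 0L)
  expect_identical(heart$id, "2034997023")
  # tetralogy rows are grouped in morphology/site pairs
  tet <- dplyr::filter(rel, sourceId == "86299006", typeId != "116680003")
  expect_identical(sort(unique(tet$relationshipGroup)), 1:4)
  expect_true(all(table(tet$relationshipGroup) == 2))
  # the ungrouped variant puts them all in group 0
  tet0 <- dplyr::filter(paper_fixture(tetralogy_grouped = FALSE)$relationships,
                        sourceId == "86299006", typeId != "116680003")
  expect_true(all(tet0$relationshipGroup == 0L))
})

test_that("the manifest distinguishes stated from invented structure", {
  m <- fixture_manifest()
  expect_false(any(m$synthetic[m$source == "73211009" & m$kind == "is_a"]))
  expect_true(all(m$synthetic[m$source == "86299006" & m$kind == "attribute"]))
})

test_that("random taxonomies are deterministic under a seed", {
  a <- random_taxonomy(fixture_config(seed = 1, n_concepts = 10))
  b <- random_taxonomy(fixture_config(seed = 1, n_concepts = 10))
  expect_identical(a$relationships, b$relationships)
  c <- random_taxonomy(fixture_config(seed = 2, n_concepts = 10))
  expect_false(identical(a$relationships, c$relationships))
})

test_that("random taxonomies are acyclic by topological sort", {
  for (seed in c(3, 11, 12)) {
    snap <- random_taxonomy(fixture_config(seed = seed, n_concepts = 50))
    isa <- dplyr::filter(snap$relationships, typeId == "116680003")
    expect_true(is_acyclic_kahn(
      tibble::tibble(child = isa$sourceId, parent = isa$destinationId),
      snap$concepts$id))
  }
})

test_that("grouped_fraction = 0 produces only ungrouped non-IS_A rows", {
  snap <- random_taxonomy(fixture_config(seed = 4, n_concepts = 30,
                                         grouped_fraction = 0))
  non_isa <- dplyr::filter(snap$relationships, typeId != "116680003")
  expect_gt(nrow(non_isa), 0)
  expect_true(all(non_isa$relationshipGroup == 0L))
})

test_that("output size matches the configuration", {
  cfg <- fixture_config(seed = 5, n_concepts = 37, n_attribute_types = 4)
  snap <- random_taxonomy(cfg)
  expect_equal(nrow(snap$concepts), 37 + 4 + 1) # concepts + attributes + root
  expect_silent(validate_snapshot(snap))
})
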
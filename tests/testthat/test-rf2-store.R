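test_that("reading header-only files yields an empty snapshot", {
  dir <- withr::local_tempdir()
  paths <- write_snapshot(rf2_snapshot(), dir)
  snap <- read_snapshot(paths[["concept"]], paths[["description"]],
                        paths[["relationship"]])
  expect_equal(nrow(snap$concepts), 0)
  expect_equal(nrow(snap$descriptions), 0)
  expect_equal(nrow(snap$relationships), 0)
})

test_that("write then read round-trips the paper fixture byte-identically", {
  snap <- paper_fixture()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_snapshot(snap, d1)
  back <- read_snapshot(p1[["concept"]], p1[["description"]],
                        p1[["relationship"]])
  expect_equal(dplyr::arrange(back$concepts, id),
               dplyr::arrange(snap$concepts, id))
  expect_equal(dplyr::arrange(back$relationships, id),
               dplyr::arrange(snap$relationships, id))
  p2 <- write_snapshot(back, d2)
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
                     readBin(p2[[k]], "raw", file.size(p2[[k]])))
  }
})

test_that("the written relationship file carries the heart-disease row", {
  dir <- withr::local_tempdir()
  paths <- write_snapshot(paper_fixture(), dir)
  lines <- readLines(paths[["relationship"]])
  expect_true(any(grepl("56265001\t80891009\t0\t363698007", lines,
                        fixed = TRUE)))
})

test_that("validation rejects broken snapshots", {
  snap <- paper_fixture()
  dup <- snap
  dup$concepts <- dplyr::bind_rows(dup$concepts, dup$concepts[1, ])
  expect_error(validate_snapshot(dup), "duplicate concept id")

  dangling <- snap
  dangling$relationships$destinationId[1] <- "999999999"
  expect_error(validate_snapshot(dangling), "not in Concept table")

  grouped_isa <- snap
  i <- which(grouped_isa$relationships$typeId == "116680003")[1]
  grouped_isa$relationships$relationshipGroup[i] <- 2L
  expect_error(validate_snapshot(grouped_isa), "relationshipGroup 0")

  bad_status <- snap
  bad_status$concepts$definitionStatusId[1] <- "12345"
  expect_error(validate_snapshot(bad_status), "definitionStatusId")
})

test_that("reading a file with a wrong column count reports the table", {
  dir <- withr::local_tempdir()
  paths <- write_snapshot(rf2_snapshot(), dir)
  writeLines(c("id\teffectiveTime", "1\t2"), paths[["concept"]])
  expect_error(read_snapshot(paths[["concept"]], paths[["description"]],
                             paths[["relationship"]]),
               "expected columns")
})

test_that("fixture ancestors include the printed supertypes", {
  idx <- taxonomy_index(paper_fixture())
  expect_true(all(c("126877002", "362969004") %in%
                    ancestors(idx, "73211009")))
  expect_true(is_a_or_self(idx, "73211009", "404684003"))
  expect_true(is_a_or_self(idx, "73211009", "73211009"))
  # a root concept has no ancestors
  expect_identical(ancestors(idx, "138875005"), character(0))
})

test_that("ancestor closure equals boolean-matrix squaring on random taxonomies", {
  for (seed in c(7, 1:9)) {
    snap <- random_taxonomy(fixture_config(seed = seed, n_concepts = 40))
    idx <- taxonomy_index(snap)
    isa <- dplyr::filter(snap$relationships, typeId == "116680003",
                         active == "1")
    ids <- sort(snap$concepts$id)
    closure <- closure_by_squaring(
      tibble::tibble(child = isa$sourceId, parent = isa$destinationId), ids)
    for (c in ids) {
      expect_setequal(ancestors(idx, c), setdiff(ids[closure[c, ]], c))
    }
  }
})

test_that("inactive IS_A rows are excluded from the index unless requested", {
  snap <- paper_fixture()
  i <- which(snap$relationships$typeId == "116680003" &
               snap$relationships$sourceId == "73211009")
  snap$relationships$active[i] <- "0"
  idx <- taxonomy_index(snap)
  expect_identical(ancestors(idx, "73211009"), character(0))
  idx2 <- taxonomy_index(snap, include_inactive = TRUE)
  expect_true("126877002" %in% ancestors(idx2, "73211009"))
})

test_that("a cyclic hierarchy is rejected with a named cycle", {
  snap <- paper_fixture()
  snap$relationships <- dplyr::bind_rows(
    snap$relationships,
    tibble::tibble(id = "890000001021", effectiveTime = "20150731",
                   active = "1", moduleId = "900000000000207008",
                   sourceId = "126877002", destinationId = "73211009",
                   relationshipGroup = 0L, typeId = "116680003",
                   characteristicTypeId = "900000000000011006",
                   modifierId = "900000000000451002"))
  expect_error(taxonomy_index(snap), "cyclic.*73211009|cyclic.*126877002")
})
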
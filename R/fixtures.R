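# Self-contained RF2 fixtures: a deterministic miniature snapshot holding
# every concept and relationship used by the worked compositional-grammar
# examples, plus seeded random taxonomies for stress and oracle testing.
# No licensed SNOMED CT release is required anywhere in the package.

# The 19 top-level hierarchy concepts of the 2015-style release, each a
# direct child of the SNOMED CT root concept.
sct_top_level <- function() {
  tibble::tribble(
    ~id,         ~label,
    "404684003", "clinical finding",
    "71388002",  "procedure",
    "363787002", "observable entity",
    "123037004", "body structure",
    "410607006", "organism",
    "105590001", "substance",
    "373873005", "pharmaceutical / biologic product",
    "123038009", "specimen",
    "260787004", "physical object",
    "78621006",  "physical force",
    "272379006", "event",
    "308916002", "environment or geographical location",
    "48176007",  "social context",
    "243796009", "situation with explicit context",
    "370115009", "special concept",
    "254291000", "staging and scales",
    "106237007", "linkage concept",
    "362981000", "qualifier value",
    "419891008", "record artifact"
  )
}

# Concept inventory of the paper-style fixture. `parents` is a
# space-separated list of IS_A targets; `stated` flags (aligned with
# `parents`) mark edges printed in the worked examples, versus edges the
# fixture invents to give each concept a home under the right top-level
# hierarchy. Invented edges surface as synthetic = TRUE in the manifest.
fixture_concepts <- function() {
  extra <- tibble::tribble(
    ~id, ~label, ~parents, ~stated,
    SCT_ROOT,      "SNOMED CT Concept", "", "",
    "246061005",   "attribute", "106237007", "F",
    "410662002",   "concept model attribute", "246061005", "T",
    "116680003",   "is a", "410662002", "F",
    "363698007",   "finding site", "410662002", "F",
    "405815000",   "procedure device", "410662002", "F",
    "260686004",   "method", "410662002", "F",
    "405813007",   "procedure site - direct", "410662002", "F",
    "116676008",   "associated morphology", "410662002", "F",
    "411116001",   "has dose form", "410662002", "F",
    "127489000",   "has active ingredient", "410662002", "F",
    "246456000",   "episodicity", "410662002", "F",
    "246075003",   "causative agent", "410662002", "F",
    "272741003",   "laterality", "410662002", "F",
    "111115",      "has basis of strength", "410662002", "F",
    "73211009",    "Diabetes mellitus", "126877002 362969004", "T T",
    "126877002",   "disorder of glucose metabolism", "404684003", "F",
    "362969004",   "disorder of endocrine system", "404684003", "F",
    "113331007",   "structure of endocrine system", "123037004", "F",
    "7246002",     "Kidney biopsy", "71388002", "F",
    "129249002",   "Needle biopsy", "71388002", "F",
    "125605004",   "Fracture of bone", "404684003", "F",
    "181940002",   "Radius", "123037004", "F",
    "122456005",   "laser device", "260787004", "F",
    "129304002",   "excision - action", "362981000", "F",
    "15497006",    "ovarian structure", "123037004", "F",
    "111613008",   "closed skull fracture with intracranial injury",
                   "451000119106 371162008", "T T",
    "451000119106", "closed injury of head", "404684003", "F",
    "371162008",   "closed fracture of skull", "404684003", "F",
    "450695007",   "closed traumatic abnormality", "123037004", "F",
    "128319008",   "intracranial structure", "123037004", "F",
    "20946005",    "fracture, closed", "123037004", "F",
    "89546000",    "bone structure of cranium", "123037004", "F",
    "27658006",    "amoxicillin", "373873005", "F",
    "385049006",   "capsule", "362981000", "F",
    "372687004",   "amoxicillin", "105590001", "F",
    "258684004",   "mg", "362981000", "F",
    "274640006",   "fever with chills", "404684003", "F",
    "81591007",    "periodic", "362981000", "T",
    "87628006",    "bacterial infectious disease", "404684003", "F",
    "9861002",     "streptococcus pneumonia", "410607006", "F",
    "45653009",    "structure of upper lobe of lung", "123037004", "F",
    "7771000",     "left", "362981000", "F",
    "56265001",    "heart disease", "404684003", "F",
    "80891009",    "heart structure", "123037004", "F",
    "86299006",    "tetralogy of Fallot", "56265001", "F",
    # Synthetic morphology/site pairs backing the tetralogy-of-Fallot
    # relationship groups (the worked example names the anatomy in prose).
    "910000001",   "ventricular septal defect (synthetic)", "123037004", "F",
    "910000002",   "interventricular septum structure (synthetic)", "123037004", "F",
    "910000003",   "stenosis (synthetic)", "123037004", "F",
    "910000004",   "pulmonary valve structure (synthetic)", "123037004", "F",
    "910000005",   "overriding structures (synthetic)", "123037004", "F",
    "910000006",   "thoracic aorta structure (synthetic)", "123037004", "F",
    "910000007",   "hypertrophy (synthetic)", "123037004", "F",
    "910000008",   "right cardiac ventricular structure (synthetic)", "123037004", "F"
  )
  top <- mutate(sct_top_level(), parents = SCT_ROOT, stated = "T")
  bind_rows(extra, top) |>
    mutate(
      parents = map(strsplit(.data$parents, " ", fixed = TRUE),
                    function(p) p[nzchar(p)]),
      stated = map(strsplit(.data$stated, " ", fixed = TRUE),
                   function(s) s[nzchar(s)] == "T"),
      status = if_else(.data$id %in% c("111613008", "86299006"),
                       SCT_FULLY_DEFINED, SCT_PRIMITIVE)
    )
}

#' Deterministic miniature RF2 snapshot for the worked examples
#'
#' Builds a small, fully self-contained snapshot holding every concept,
#' description (fully specified name as printed), and relationship used by
#' the worked compositional-grammar examples: the diabetes-mellitus and
#' heart-disease finding-site rows, the grouped definition of closed skull
#' fracture with intracranial injury, and the tetralogy-of-Fallot
#' morphology/finding-site relationship groups. Hierarchy edges that the
#' examples do not state are invented so that every concept sits under the
#' right top-level hierarchy; those edges are flagged in the manifest
#' (`attr(x, "manifest")`, also via [fixture_manifest()]) with
#' `synthetic = TRUE`.
#'
#' @param tetralogy_grouped Emit the tetralogy-of-Fallot rows with their
#'   relationship groups (`TRUE`, the grouped modeling) or all in group 0
#'   (`FALSE`, the ungrouped modeling that motivates grouping).
#' @return A validated [rf2_snapshot()] with a `manifest` attribute.
#' @export
paper_fixture <- function(tetralogy_grouped = TRUE) {
  inv <- fixture_concepts()
  concepts <- tibble(
    id = inv$id, effectiveTime = "20150731", active = "1",
    moduleId = SCT_DEFAULT_MODULE, definitionStatusId = inv$status
  )
  descriptions <- tibble(
    id = sprintf("7%08d011", seq_len(nrow(inv))),
    effectiveTime = "20150731", active = "1", moduleId = SCT_DEFAULT_MODULE,
    conceptId = inv$id, languageCode = "en", typeId = SCT_FSN_TYPE,
    term = inv$label, caseSignificanceId = "900000000000448009"
  )

  isa <- tidyr::unnest(
    select(inv, source = "id", destination = "parents", stated = "stated"),
    cols = c("destination", "stated"))
  isa_rows <- tibble(
    sourceId = isa$source, destinationId = isa$destination,
    relationshipGroup = 0L, typeId = SCT_IS_A
  )

  tet_groups <- if (tetralogy_grouped) 1:4 else rep(0L, 4)
  attr_rows <- tibble::tribble(
    ~sourceId, ~typeId, ~destinationId, ~relationshipGroup,
    "56265001",  "363698007", "80891009",  0L,  # heart disease finding site
    "73211009",  "363698007", "113331007", 0L,  # diabetes finding site
    "111613008", "116676008", "450695007", 1L,
    "111613008", "363698007", "128319008", 1L,
    "111613008", "116676008", "20946005",  2L,
    "111613008", "363698007", "89546000",  2L,
    "86299006",  "116676008", "910000001", tet_groups[1],
    "86299006",  "363698007", "910000002", tet_groups[1],
    "86299006",  "116676008", "910000003", tet_groups[2],
    "86299006",  "363698007", "910000004", tet_groups[2],
    "86299006",  "116676008", "910000005", tet_groups[3],
    "86299006",  "363698007", "910000006", tet_groups[3],
    "86299006",  "116676008", "910000007", tet_groups[4],
    "86299006",  "363698007", "910000008", tet_groups[4]
  ) |> mutate(relationshipGroup = as.integer(.data$relationshipGroup))

  # The heart-disease finding-site row keeps its published relationship id;
  # every other row id is synthetic and deterministic.
  n_isa <- nrow(isa_rows)
  rel_ids <- c(sprintf("8%08d021", seq_len(n_isa)),
               "2034997023",
               sprintf("8%08d025", seq_len(nrow(attr_rows) - 1L)))
  all_rows <- bind_rows(isa_rows, attr_rows)
  relationships <- tibble(
    id = rel_ids,
    effectiveTime = "20150731", active = "1", moduleId = SCT_DEFAULT_MODULE,
    sourceId = all_rows$sourceId, destinationId = all_rows$destinationId,
    relationshipGroup = all_rows$relationshipGroup, typeId = all_rows$typeId,
    characteristicTypeId = SCT_STATED, modifierId = SCT_EXISTENTIAL_MODIFIER
  )

  snap <- rf2_snapshot(concepts, descriptions, relationships)
  manifest <- bind_rows(
    tibble(kind = "is_a", source = isa$source, destination = isa$destination,
           synthetic = !isa$stated),
    tibble(kind = "attribute", source = attr_rows$sourceId,
           destination = attr_rows$destinationId,
           synthetic = attr_rows$sourceId == "86299006")
  )
  attr(snap, "manifest") <- manifest
  snap
}

#' Manifest of paper-stated versus fixture-invented structure
#'
#' @param snapshot A snapshot produced by [paper_fixture()].
#' @return A tibble with one row per fixture relationship (`kind`, `source`,
#'   `destination`, `synthetic`); `synthetic = TRUE` marks structure the
#'   fixture invents beyond what the worked examples state.
#' @export
fixture_manifest <- function(snapshot = paper_fixture()) {
  m <- attr(snapshot, "manifest")
  if (is.null(m)) abort("snapshot carries no fixture manifest")
  m
}

#' Configuration for random taxonomy generation
#'
#' @param seed Integer seed; the generator is fully deterministic under it.
#' @param n_concepts Number of domain concepts (excluding the synthetic root
#'   and attribute-type concepts); at least 1.
#' @param n_attribute_types Number of synthetic attribute-type concepts used
#'   as `typeId` of non-IS_A rows.
#' @param max_parents Maximum IS_A parents per concept; at least 1.
#' @param grouped_fraction Proportion in `[0, 1]` of non-IS_A rows assigned
#'   to shared non-zero relationship groups per source concept.
#' @param relationship_rate Expected number of non-IS_A rows per concept.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_concepts = 50L,
                           n_attribute_types = 3L, max_parents = 3L,
                           grouped_fraction = 0.3, relationship_rate = 1) {
  stopifnot(n_concepts >= 1, max_parents >= 1, n_attribute_types >= 1,
            grouped_fraction >= 0, grouped_fraction <= 1)
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 n_attribute_types = as.integer(n_attribute_types),
                 max_parents = as.integer(max_parents),
                 grouped_fraction = grouped_fraction,
                 relationship_rate = relationship_rate),
            class = "fixture_config")
}

#' Generate a seeded random taxonomy snapshot
#'
#' Produces an acyclic IS_A DAG rooted at a single synthetic root: concept
#' `i` picks its parents uniformly among strictly earlier concepts, which
#' guarantees acyclicity by construction. Non-IS_A rows draw their `typeId`
#' from synthetic attribute-type concepts; a `grouped_fraction` share of
#' them is bundled into shared non-zero relationship groups (pairs or
#' triples) per source concept. Identical configs give identical snapshots.
#'
#' @param config A [fixture_config()].
#' @return A validated [rf2_snapshot()].
#' @export
random_taxonomy <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, random_taxonomy_impl(config))
}

random_taxonomy_impl <- function(config) {
  n <- config$n_concepts
  root <- "1000000"
  ids <- as.character(1000000 + seq_len(n))
  attr_ids <- as.character(2000000 + seq_len(config$n_attribute_types))
  all_ids <- c(root, ids, attr_ids)

  concepts <- tibble(
    id = all_ids, effectiveTime = "20150731", active = "1",
    moduleId = SCT_DEFAULT_MODULE, definitionStatusId = SCT_PRIMITIVE
  )
  descriptions <- tibble(
    id = sprintf("3%07d011", seq_along(all_ids)),
    effectiveTime = "20150731", active = "1", moduleId = SCT_DEFAULT_MODULE,
    conceptId = all_ids, languageCode = "en", typeId = SCT_FSN_TYPE,
    term = c("synthetic root",
             sprintf("synthetic concept %d", seq_len(n)),
             sprintf("synthetic attribute %d", seq_len(config$n_attribute_types))),
    caseSignificanceId = "900000000000448009"
  )

  isa <- purrr::map_dfr(seq_len(n), function(i) {
    pool <- c(root, ids[seq_len(i - 1L)])
    k <- sample.int(min(config$max_parents, length(pool)), 1L)
    tibble(sourceId = ids[i],
           destinationId = sample(pool, k),
           relationshipGroup = 0L, typeId = SCT_IS_A)
  })
  isa_attr <- tibble(sourceId = attr_ids, destinationId = root,
                     relationshipGroup = 0L, typeId = SCT_IS_A)

  n_rel <- stats::rpois(1L, config$relationship_rate * n)
  non_isa <- tibble(
    sourceId = if (n_rel > 0) sample(ids, n_rel, replace = TRUE) else character(),
    destinationId = if (n_rel > 0) sample(ids, n_rel, replace = TRUE) else character(),
    relationshipGroup = integer(n_rel),
    typeId = if (n_rel > 0) sample(attr_ids, n_rel, replace = TRUE) else character()
  )
  if (nrow(non_isa) > 0 && config$grouped_fraction > 0) {
    grouped <- stats::runif(nrow(non_isa)) < config$grouped_fraction
    non_isa <- non_isa |>
      group_by(.data$sourceId) |>
      mutate(relationshipGroup = assign_groups(grouped[dplyr::cur_group_rows()])) |>
      ungroup()
  }

  rel <- bind_rows(isa, isa_attr, non_isa)
  relationships <- tibble(
    id = sprintf("4%07d021", seq_len(nrow(rel))),
    effectiveTime = "20150731", active = "1", moduleId = SCT_DEFAULT_MODULE,
    sourceId = rel$sourceId, destinationId = rel$destinationId,
    relationshipGroup = rel$relationshipGroup, typeId = rel$typeId,
    characteristicTypeId = SCT_STATED, modifierId = SCT_EXISTENTIAL_MODIFIER
  )
  rf2_snapshot(concepts, descriptions, relationships)
}

# Bundle the TRUE-flagged rows of one source concept into groups of 2-3;
# a leftover single grouped row still gets its own non-zero group number.
assign_groups <- function(grouped) {
  out <- integer(length(grouped))
  idx <- which(grouped)
  g <- 0L
  while (length(idx) > 0) {
    g <- g + 1L
    take <- utils::head(idx, sample(2:3, 1L))
    out[take] <- g
    idx <- setdiff(idx, take)
  }
  out
}
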
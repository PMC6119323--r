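# The upper-level ontology artifact: an OGMS/BFO-aligned scaffold with the
# reified Component/Concept/Description/Relationship schema (8 object and
# 20 data properties), disjointness over the top-level hierarchies, and the
# machinery to pour RF2 content and compositional-grammar expressions into
# it. The OGMS/BFO classes are label-only stubs (synthetic stand-ins; the
# real upper ontologies are not imported).

# ---- OWL class expressions -------------------------------------------------

owl_cexpr <- function(variant, fields) {
  structure(c(list(variant = variant), fields), class = "owl_cexpr")
}

o_ref <- function(iri) owl_cexpr("ref", list(iri = iri))
o_and <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1L]]) &&
      !inherits(members[[1L]], "owl_cexpr")) {
    members <- members[[1L]]
  }
  if (length(members) == 1L) return(members[[1L]])
  owl_cexpr("and", list(members = members))
}
o_some <- function(prop, expr) owl_cexpr("some", list(prop = prop, expr = expr))
o_only <- function(prop, expr) owl_cexpr("only", list(prop = prop, expr = expr))
o_exactly <- function(n, prop, expr) {
  owl_cexpr("exactly", list(n = n, prop = prop, expr = expr))
}
o_dataval <- function(prop, value) {
  owl_cexpr("dataval", list(prop = prop, value = value))
}

owl_axiom <- function(kind, subject = NULL, expr = NULL, members = NULL) {
  structure(list(kind = kind, subject = subject, expr = expr,
                 members = members),
            class = "owl_axiom")
}

# ---- ontology container ----------------------------------------------------

#' Ontology construction options
#'
#' @param iri_base Namespace for the ontology's IRIs; local names use the
#'   `SCTO_<conceptId>` format.
#' @param reification `"component"` (default: relationship and description
#'   rows become individuals under a SNOMED CT component schema -- the more
#'   formal and straightforward pattern) or `"nary"` (the class-per-
#'   relationship n-ary pattern with ONLY restrictions, supported as an
#'   alternate emitter mode).
#' @return An `scto_config`.
#' @export
scto_config <- function(iri_base = "https://example.org/scto#",
                        reification = c("component", "nary")) {
  structure(list(iri_base = iri_base,
                 reification = match.arg(reification)),
            class = "scto_config")
}

empty_ontology <- function(config = scto_config()) {
  structure(list(
    config = config,
    classes = tibble(iri = character(), label = character(),
                     definition = character()),
    object_properties = tibble(name = character(), definition = character(),
                               domain = character(), range = character(),
                               inverse_of = character(),
                               characteristics = character()),
    data_properties = tibble(name = character(), definition = character(),
                             domain = character(), range = character(),
                             functional = logical()),
    class_axioms = list(),
    individuals = tibble(id = character(), type = character()),
    assertions = tibble(subject = character(), property = character(),
                        object = character()),
    data_assertions = tibble(subject = character(), property = character(),
                             value = character(), datatype = character()),
    grouped_relations = tibble(r1 = character(), r2 = character()),
    rules = list()
  ), class = "scto_ontology")
}

#' @export
print.scto_ontology <- function(x, ...) {
  cat(sprintf(paste0("<scto_ontology> %d classes, %d object properties, ",
                     "%d data properties, %d class axioms, %d individuals\n"),
              nrow(x$classes), nrow(x$object_properties),
              nrow(x$data_properties), length(x$class_axioms),
              nrow(x$individuals)))
  invisible(x)
}

ont_add_class <- function(ont, iri, label, definition) {
  if (!(iri %in% ont$classes$iri)) {
    ont$classes <- add_row(ont$classes, iri = iri, label = label,
                           definition = definition)
  }
  ont
}

ont_add_axiom <- function(ont, ax) {
  key <- axiom_key(ax)
  keys <- map_chr(ont$class_axioms, axiom_key)
  if (!(key %in% keys)) ont$class_axioms <- c(ont$class_axioms, list(ax))
  ont
}

axiom_key <- function(ax) {
  paste(ax$kind, ax$subject %||% "",
        if (!is.null(ax$expr)) cexpr_key(ax$expr) else "",
        if (!is.null(ax$members)) paste(sort(ax$members), collapse = ","))
}

cexpr_key <- function(e) {
  switch(e$variant,
    ref = e$iri,
    and = paste0("and(", paste(sort(map_chr(e$members, cexpr_key)),
                               collapse = ","), ")"),
    some = paste0("some(", e$prop, ",", cexpr_key(e$expr), ")"),
    only = paste0("only(", e$prop, ",", cexpr_key(e$expr), ")"),
    exactly = paste0("exactly(", e$n, ",", e$prop, ",", cexpr_key(e$expr), ")"),
    dataval = paste0("dataval(", e$prop, ",", e$value, ")")
  )
}

sct_iri <- function(id) paste0("SCTO_", id)

# ---- default mapping table -------------------------------------------------

#' Default mapping of top-level concepts to upper-level classes
#'
#' One row per top-level hierarchy concept (19 rows) plus the root concept.
#' `kind` is one of `subsumption` (the concept is a subclass of the named
#' upper-level stub), `equivalence`, `child_of_root` (attached under the
#' root concept only, with no upper-level target -- the linkage-concept
#' bookkeeping case), or `excluded` (not modeled: the three hierarchies
#' whose semantics cannot be placed under an upper-level universal). The
#' defaults give 14 subsumption and 2 equivalence mappings over 17 mapped
#' entries; the exact upper-level target of each entry is configuration,
#' not doctrine.
#'
#' @return Tibble with columns `sct_id`, `sct_label`, `upper_class`, `kind`.
#' @export
default_mapping <- function() {
  tibble::tribble(
    ~sct_id,      ~sct_label,                             ~upper_class,                 ~kind,
    "138875005",  "SNOMED CT Concept",                    "entity",                     "subsumption",
    "404684003",  "clinical finding",                     "disorder",                   "subsumption",
    "71388002",   "procedure",                            "health care process",        "subsumption",
    "363787002",  "observable entity",                    "quality",                    "subsumption",
    "123037004",  "body structure",                       "anatomical entity",          "subsumption",
    "410607006",  "organism",                             "organism",                   "equivalence",
    "105590001",  "substance",                            "material entity",            "subsumption",
    "373873005",  "pharmaceutical / biologic product",    "material entity",            "subsumption",
    "123038009",  "specimen",                             "specimen",                   "subsumption",
    "260787004",  "physical object",                      "object",                     "equivalence",
    "78621006",   "physical force",                       "occurrent",                  "subsumption",
    "272379006",  "event",                                "process",                    "subsumption",
    "308916002",  "environment or geographical location", "site",                       "subsumption",
    "254291000",  "staging and scales",                   "information content entity", "subsumption",
    "419891008",  "record artifact",                      "information content entity", "subsumption",
    "362981000",  "qualifier value",                      "data item",                  "subsumption",
    "106237007",  "linkage concept",                      NA_character_,                "child_of_root",
    "48176007",   "social context",                       NA_character_,                "excluded",
    "243796009",  "situation with explicit context",      NA_character_,                "excluded",
    "370115009",  "special concept",                      NA_character_,                "excluded"
  )
}

#' Validate a mapping table
#'
#' Checks the structural invariants: every one of the 19 top-level
#' hierarchy concepts appears exactly once, exactly 3 entries are excluded,
#' and the mapped entries split into 14 subsumption, 2 equivalence, and 1
#' child-of-root mapping.
#'
#' @param mapping A tibble like [default_mapping()].
#' @return The mapping, invisibly; errors on violation.
#' @export
validate_mapping <- function(mapping) {
  top <- sct_top_level()$id
  counts <- table(factor(mapping$sct_id, levels = unique(mapping$sct_id)))
  if (any(counts > 1)) {
    abort(sprintf("mapping lists id(s) more than once: %s",
                  paste(names(counts)[counts > 1], collapse = ", ")))
  }
  missing <- setdiff(top, mapping$sct_id)
  if (length(missing) > 0) {
    abort(sprintf("mapping must cover all 19 top-level concepts; missing: %s",
                  paste(missing, collapse = ", ")))
  }
  kinds <- table(factor(mapping$kind,
                        levels = c("subsumption", "equivalence",
                                   "child_of_root", "excluded")))
  expected <- c(subsumption = 14L, equivalence = 2L, child_of_root = 1L,
                excluded = 3L)
  if (!identical(as.integer(kinds[names(expected)]), unname(expected))) {
    abort(sprintf(
      "mapping kind counts must be 14 subsumption / 2 equivalence / 1 child-of-root / 3 excluded, found %s",
      paste(sprintf("%d %s", as.integer(kinds), names(kinds)), collapse = " / ")))
  }
  invisible(mapping)
}

#' Summary statistics of a mapping table
#'
#' @param mapping A tibble like [default_mapping()].
#' @return One-row tibble: number of top-level concepts covered, number
#'   modeled (not excluded), number of mapped entries, and the percentage
#'   share of subsumption, equivalence, and no-equivalence mappings among
#'   the mapped entries.
#' @export
mapping_summary <- function(mapping = default_mapping()) {
  validate_mapping(mapping)
  top <- sct_top_level()$id
  top_rows <- filter(mapping, .data$sct_id %in% top)
  mapped <- filter(mapping, .data$kind != "excluded")
  tibble(
    covered_top_level = nrow(top_rows),
    modeled = sum(top_rows$kind != "excluded"),
    mapped_entries = nrow(mapped),
    subsumption_pct = 100 * sum(mapped$kind == "subsumption") / nrow(mapped),
    equivalence_pct = 100 * sum(mapped$kind == "equivalence") / nrow(mapped),
    no_equivalence_pct = 100 * sum(mapped$kind == "child_of_root") / nrow(mapped)
  )
}

# Label-only stub tree standing in for the OGMS/BFO upper level (synthetic;
# the real upper ontologies are not imported). label -> parent label.
upper_level_stubs <- function() {
  tibble::tribble(
    ~label,                          ~parent,
    "entity",                        NA_character_,
    "continuant",                    "entity",
    "occurrent",                     "entity",
    "independent continuant",        "continuant",
    "specifically dependent continuant", "continuant",
    "generically dependent continuant",  "continuant",
    "material entity",               "independent continuant",
    "immaterial entity",             "independent continuant",
    "site",                          "immaterial entity",
    "object",                        "material entity",
    "organism",                      "material entity",
    "anatomical entity",             "material entity",
    "specimen",                      "material entity",
    "disorder",                      "material entity",
    "quality",                       "specifically dependent continuant",
    "disposition",                   "specifically dependent continuant",
    "disease",                       "disposition",
    "information content entity",    "generically dependent continuant",
    "data item",                     "information content entity",
    "process",                       "occurrent",
    "health care process",           "process",
    "pathological process",          "process"
  )
}

stub_iri <- function(label) {
  paste0("U_", gsub("[^A-Za-z0-9]+", "_", label))
}

# The 15 hierarchy classes of the pairwise-disjointness axiom (a class
# cannot sit under more than one top-level hierarchy).
disjoint_hierarchy_ids <- function() {
  c("373873005", "78621006", "106237007", "308916002", "362981000",
    "363787002", "419891008", "71388002", "272379006", "123038009",
    "105590001", "254291000", "260787004", "404684003", "410607006")
}

# ---- scaffold --------------------------------------------------------------

object_property_table <- function() {
  tibble::tribble(
    ~name, ~definition, ~domain, ~range, ~inverse_of, ~characteristics,
    "Has_description", "Determines a description for a class.",
      "SCTO_138875005", "SCTO_Description", "IsDescriptionOf", "",
    "IsDescriptionOf", "Is the inverse of Has_description.",
      "SCTO_Description", "SCTO_138875005", "Has_description", "",
    "Relationship_destinationId",
      "Identifies the class that is the destination of the relationship. Set to an identifier of a concept in the Concept file.",
      "SCTO_Relationship", "SCTO_138875005", "IsDestinationOf", "",
    "Relationship_sourceId",
      "Identifies the source concept of the relationship. Set to an identifier of a concept in the Concept file.",
      "SCTO_Relationship", "SCTO_138875005", "IsSourceOf", "",
    "Relationship_typeId",
      "A concept enumeration value from the metadata hierarchy that identifies the semantic type of the relationship. It is a subtype of the concept model attribute hierarchy.",
      "SCTO_Relationship", "SCTO_106237007", "", "",
    "IsSourceOf",
      "Determines the source of a relationship. It is the inverse of Relationship_sourceId.",
      "SCTO_138875005", "SCTO_Relationship", "Relationship_sourceId", "",
    "IsDestinationOf",
      "Determines the destination of a relationship. It is the inverse of Relationship_destinationId.",
      "SCTO_138875005", "SCTO_Relationship", "Relationship_destinationId", "",
    "Grouped_Relations",
      "Used to explicitly determine the grouped relationships.",
      "SCTO_Relationship", "SCTO_Relationship", "", "Symmetric"
  )
}

data_property_table <- function() {
  rf2_fields <- list(
    Concept = c("Id", "effectiveTime", "active", "moduleId",
                "definitionStatusId"),
    Description = c("id", "effectiveTime", "active", "moduleId",
                    "languageCode", "typeId", "term", "caseSignificanceId"),
    Relationship = c("id", "effectiveTime", "active", "moduleId",
                     "relationshipGroup", "characteristicTypeId", "modifierId")
  )
  domains <- c(Concept = "SCTO_138875005", Description = "SCTO_Description",
               Relationship = "SCTO_Relationship")
  purrr::map_dfr(names(rf2_fields), function(tb) {
    fields <- rf2_fields[[tb]]
    tibble(
      name = paste0(tb, "_", fields),
      definition = sprintf("The %s field of the %s record, preserved from the release file.",
                           fields, tolower(tb)),
      domain = domains[[tb]],
      range = case_when(fields == "relationshipGroup" ~ "xsd:integer",
                        fields == "active" ~ "xsd:boolean",
                        TRUE ~ "xsd:string"),
      functional = TRUE
    )
  })
}

#' Build the upper-level ontology scaffold
#'
#' Constructs the fresh artifact: the `SNOMED CT component` root with its
#' three subclasses (Concept, Description, Relationship), the label-only
#' OGMS/BFO stub tree, the root concept placed under `entity`, the 16
#' modeled top-level hierarchy classes attached according to the mapping
#' (plus the linkage concept under the root concept only), the 8 object
#' properties and 20 data properties of the reified schema, one
#' pairwise-disjointness axiom over the 15 hierarchy classes, the
#' relationship-grouping rule record, and a label plus textual-definition
#' annotation for every class and property.
#'
#' @param mapping A mapping table (validated); see [default_mapping()].
#' @param config An [scto_config()].
#' @return An `scto_ontology`.
#' @export
build_scaffold <- function(mapping = default_mapping(),
                           config = scto_config()) {
  validate_mapping(mapping)
  ont <- empty_ontology(config)

  ont <- ont_add_class(ont, "SCTO_Component", "SNOMED CT component",
    "Root of the reified release schema; every concept, description, and relationship record is one of its three kinds of component.")
  for (part in c("Description", "Relationship")) {
    ont <- ont_add_class(ont, paste0("SCTO_", part),
                         paste("SNOMED CT", part),
                         sprintf("A reified %s record from the release files.",
                                 tolower(part)))
    ont <- ont_add_axiom(ont, owl_axiom("subclass",
                                        subject = paste0("SCTO_", part),
                                        expr = o_ref("SCTO_Component")))
  }

  stubs <- upper_level_stubs()
  for (i in seq_len(nrow(stubs))) {
    ont <- ont_add_class(ont, stub_iri(stubs$label[i]), stubs$label[i],
      sprintf("Upper-level stub class '%s' (label-only synthetic stand-in for the corresponding OGMS/BFO universal).",
              stubs$label[i]))
    if (!is.na(stubs$parent[i])) {
      ont <- ont_add_axiom(ont, owl_axiom("subclass",
        subject = stub_iri(stubs$label[i]),
        expr = o_ref(stub_iri(stubs$parent[i]))))
    }
  }

  root_row <- filter(mapping, .data$sct_id == SCT_ROOT)
  for (i in seq_len(nrow(mapping))) {
    row <- mapping[i, ]
    if (row$kind == "excluded") next
    iri <- sct_iri(row$sct_id)
    ont <- ont_add_class(ont, iri, row$sct_label,
      sprintf("The '%s' concept (top level of the release hierarchy).",
              row$sct_label))
    if (row$sct_id == SCT_ROOT) {
      # the root concept itself: under the component schema and the
      # upper-level entity
      ont <- ont_add_axiom(ont, owl_axiom("subclass", subject = iri,
                                          expr = o_ref("SCTO_Component")))
      ont <- ont_add_axiom(ont, owl_axiom("subclass", subject = iri,
                                          expr = o_ref(stub_iri(row$upper_class))))
      next
    }
    ont <- ont_add_axiom(ont, owl_axiom("subclass", subject = iri,
                                        expr = o_ref(sct_iri(SCT_ROOT))))
    if (row$kind == "subsumption") {
      ont <- ont_add_axiom(ont, owl_axiom("subclass", subject = iri,
                                          expr = o_ref(stub_iri(row$upper_class))))
    } else if (row$kind == "equivalence") {
      ont <- ont_add_axiom(ont, owl_axiom("equivalent", subject = iri,
                                          expr = o_ref(stub_iri(row$upper_class))))
    }
    # child_of_root: under the root concept only
  }

  ont$object_properties <- object_property_table()
  ont$data_properties <- data_property_table()

  ont <- ont_add_axiom(ont, owl_axiom(
    "disjoint", members = sct_iri(disjoint_hierarchy_ids())))

  ont$rules <- list(grouping_rule = paste(
    "Relationship_relationshipGroup(?r1, ?n1),",
    "Relationship_relationshipGroup(?r2, ?n2),",
    "Relationship_sourceId(?r1, ?c), Relationship_sourceId(?r2, ?c),",
    "notEqual(?r1, ?r2), notEqual(?n1, 0), equal(?n1, ?n2)",
    "-> Grouped_Relations(?r1, ?r2)"))
  ont
}

# ---- reification -----------------------------------------------------------

#' Reify an RF2 snapshot into the ontology
#'
#' Every concept row becomes a class `SCTO_<id>`; active IS_A rows become
#' subclass axioms (never object-property assertions); a fully defined
#' concept instead receives one equivalence over the conjunction of its
#' parents and its reified relationship restrictions. Every description row
#' becomes a Description individual carrying its record fields as data
#' properties and linked to its concept through `Has_description`; every
#' non-IS_A relationship row becomes a Relationship individual with
#' source/destination/type object links and the remaining record fields as
#' data values. Deterministic and idempotent: reifying the same snapshot
#' twice changes nothing.
#'
#' @param snapshot A validated [rf2_snapshot()].
#' @param ont An `scto_ontology` (typically a fresh [build_scaffold()]).
#' @return The enriched ontology.
#' @export
reify <- function(snapshot, ont = build_scaffold()) {
  validate_snapshot(snapshot)
  stopifnot(inherits(ont, "scto_ontology"))
  con <- snapshot$concepts
  des <- snapshot$descriptions
  rel <- snapshot$relationships
  fsn <- des[des$typeId == SCT_FSN_TYPE & des$active == "1", , drop = FALSE]
  labels <- stats::setNames(fsn$term, fsn$conceptId)

  isa <- rel[rel$typeId == SCT_IS_A & rel$active == "1", , drop = FALSE]
  non_isa <- rel[rel$typeId != SCT_IS_A, , drop = FALSE]

  for (i in order(con$id, method = "radix")) {
    cid <- con$id[i]
    lbl <- if (cid %in% names(labels)) labels[[cid]] else sct_iri(cid)
    ont <- ont_add_class(ont, sct_iri(cid), lbl,
                         sprintf("SNOMED CT concept %s.", cid))
  }
  for (i in order(con$id, method = "radix")) {
    cid <- con$id[i]
    parents <- sort(isa$destinationId[isa$sourceId == cid], method = "radix")
    if (con$definitionStatusId[i] == SCT_FULLY_DEFINED) {
      rows <- non_isa[non_isa$sourceId == cid & non_isa$active == "1", ,
                      drop = FALSE]
      parts <- c(map(parents, function(p) o_ref(sct_iri(p))),
                 reified_restrictions(rows))
      if (length(parts) > 0) {
        ont <- ont_add_axiom(ont, owl_axiom("equivalent",
          subject = sct_iri(cid), expr = o_and(parts)))
      }
    } else {
      for (p in parents) {
        ont <- ont_add_axiom(ont, owl_axiom("subclass",
          subject = sct_iri(cid), expr = o_ref(sct_iri(p))))
      }
    }
  }

  desc_ids <- sprintf("desc_%s", des$id)
  new_desc <- !(desc_ids %in% ont$individuals$id)
  ont$individuals <- bind_rows(ont$individuals,
    tibble(id = desc_ids[new_desc], type = "description"))
  desc_obj <- tibble(subject = sct_iri(des$conceptId),
                     property = "Has_description", object = desc_ids)
  desc_data <- bind_rows(
    tibble(subject = desc_ids, property = "Description_id",
           value = des$id, datatype = "xsd:string"),
    tibble(subject = desc_ids, property = "Description_effectiveTime",
           value = des$effectiveTime, datatype = "xsd:string"),
    tibble(subject = desc_ids, property = "Description_active",
           value = as.character(ifelse(des$active == "1", "true", "false")),
           datatype = "xsd:boolean"),
    tibble(subject = desc_ids, property = "Description_moduleId",
           value = des$moduleId, datatype = "xsd:string"),
    tibble(subject = desc_ids, property = "Description_languageCode",
           value = des$languageCode, datatype = "xsd:string"),
    tibble(subject = desc_ids, property = "Description_typeId",
           value = des$typeId, datatype = "xsd:string"),
    tibble(subject = desc_ids, property = "Description_term",
           value = des$term, datatype = "xsd:string"),
    tibble(subject = desc_ids, property = "Description_caseSignificanceId",
           value = des$caseSignificanceId, datatype = "xsd:string")
  )

  rel_ids <- sprintf("rel_%s", non_isa$id)
  new_rel <- !(rel_ids %in% ont$individuals$id)
  ont$individuals <- bind_rows(ont$individuals,
    tibble(id = rel_ids[new_rel], type = "relationship"))
  rel_obj <- bind_rows(
    tibble(subject = rel_ids, property = "Relationship_sourceId",
           object = sct_iri(non_isa$sourceId)),
    tibble(subject = rel_ids, property = "Relationship_destinationId",
           object = sct_iri(non_isa$destinationId)),
    tibble(subject = rel_ids, property = "Relationship_typeId",
           object = sct_iri(non_isa$typeId)),
    tibble(subject = sct_iri(non_isa$sourceId), property = "IsSourceOf",
           object = rel_ids)
  )
  rel_data <- bind_rows(
    tibble(subject = rel_ids, property = "Relationship_id",
           value = non_isa$id, datatype = "xsd:string"),
    tibble(subject = rel_ids, property = "Relationship_effectiveTime",
           value = non_isa$effectiveTime, datatype = "xsd:string"),
    tibble(subject = rel_ids, property = "Relationship_active",
           value = as.character(ifelse(non_isa$active == "1", "true", "false")),
           datatype = "xsd:boolean"),
    tibble(subject = rel_ids, property = "Relationship_moduleId",
           value = non_isa$moduleId, datatype = "xsd:string"),
    tibble(subject = rel_ids, property = "Relationship_relationshipGroup",
           value = as.character(non_isa$relationshipGroup),
           datatype = "xsd:integer"),
    tibble(subject = rel_ids, property = "Relationship_characteristicTypeId",
           value = non_isa$characteristicTypeId, datatype = "xsd:string"),
    tibble(subject = rel_ids, property = "Relationship_modifierId",
           value = non_isa$modifierId, datatype = "xsd:string")
  )

  ont$assertions <- distinct(arrange(
    bind_rows(ont$assertions, desc_obj, rel_obj),
    .data$subject, .data$property, .data$object))
  ont$data_assertions <- distinct(arrange(
    bind_rows(ont$data_assertions, desc_data, rel_data),
    .data$subject, .data$property, .data$value))
  ont
}

reified_restrictions <- function(rows) {
  if (nrow(rows) == 0) return(list())
  blocks <- list()
  ungrouped <- rows[rows$relationshipGroup == 0L, , drop = FALSE]
  for (i in seq_len(nrow(ungrouped))) {
    blocks <- c(blocks, list(o_some("IsSourceOf",
      relationship_inner(ungrouped$typeId[i], ungrouped$destinationId[i]))))
  }
  for (g in sort(unique(rows$relationshipGroup[rows$relationshipGroup > 0L]))) {
    grp <- rows[rows$relationshipGroup == g, , drop = FALSE]
    inner <- map(seq_len(nrow(grp)), function(i) {
      relationship_inner(grp$typeId[i], grp$destinationId[i])
    })
    first <- inner[[1L]]
    rest <- map(inner[-1L], function(x) o_exactly(1L, "Grouped_Relations", x))
    blocks <- c(blocks, list(o_some("IsSourceOf", o_and(c(list(first), rest)))))
  }
  blocks
}

relationship_inner <- function(type_id, destination_id) {
  o_and(list(
    o_some("Relationship_destinationId", o_ref(sct_iri(destination_id))),
    o_some("Relationship_typeId", o_ref(sct_iri(type_id)))
  ))
}

#' Materialize the relationship-grouping rule
#'
#' Applies the grouping rule directly: every pair of distinct Relationship
#' individuals sharing a source concept and an equal non-zero relationship
#' group is linked by the symmetric `Grouped_Relations` property. Group 0
#' (ungrouped) never links.
#'
#' @param ont An ontology with reified relationship individuals (see
#'   [reify()]).
#' @return The ontology with `grouped_relations` pairs filled in (each
#'   unordered pair stored once, smaller id first).
#' @export
materialize_groups <- function(ont) {
  stopifnot(inherits(ont, "scto_ontology"))
  rel <- relationship_individual_table(ont)
  grouped <- filter(rel, .data$group > 0L)
  pairs <- grouped |>
    inner_join(grouped, by = c("source", "group"),
               relationship = "many-to-many") |>
    filter(.data$id.x < .data$id.y) |>
    transmute(r1 = .data$id.x, r2 = .data$id.y) |>
    distinct() |>
    arrange(.data$r1, .data$r2)
  ont$grouped_relations <- pairs
  ont
}

# Source concept and group number of every relationship individual.
relationship_individual_table <- function(ont) {
  ids <- ont$individuals$id[ont$individuals$type == "relationship"]
  src <- ont$assertions |>
    filter(.data$property == "Relationship_sourceId",
           .data$subject %in% ids) |>
    select(id = "subject", source = "object")
  grp <- ont$data_assertions |>
    filter(.data$property == "Relationship_relationshipGroup",
           .data$subject %in% ids) |>
    transmute(id = .data$subject, group = as.integer(.data$value))
  inner_join(src, grp, by = "id")
}

# ---- expressions to axioms -------------------------------------------------

#' Convert a compositional-grammar expression to ontology axioms
#'
#' Renders an expression as one class axiom over the reified schema. In the
#' `"plain"` pattern each refinement becomes an `IsSourceOf` restriction
#' pairing a `Relationship_destinationId` with a `Relationship_typeId`
#' filler; in the `"reified"` pattern the members of each attribute group
#' are additionally chained by `Grouped_Relations exactly 1` linkages so
#' the group structure is visible to a reasoner. The axiom kind follows the
#' expression's definition status. Concrete values become data-property
#' restrictions on an expression-local data property (declared on demand).
#'
#' @param expr A `cg_expression` (or expression string).
#' @param ont The target ontology; all referenced SCTIDs must already be
#'   classes.
#' @param pattern `"plain"` or `"reified"`.
#' @param label Label for the new class; defaults to the expression's
#'   defined-concept term when present.
#' @return The ontology with the new class and axiom added.
#' @export
expression_to_axioms <- function(expr, ont, pattern = c("plain", "reified"),
                                 label = NULL) {
  pattern <- match.arg(pattern)
  if (is.character(expr)) expr <- parse_cg(expr)
  stopifnot(inherits(expr, "cg_expression"), inherits(ont, "scto_ontology"))

  referenced <- cg_referenced_ids(expr)
  missing <- setdiff(sct_iri(referenced), ont$classes$iri)
  if (length(missing) > 0) {
    abort(sprintf("expression references unknown class(es): %s",
                  paste(missing, collapse = ", ")))
  }

  defined <- expr$defined
  if (!is.null(defined) && inherits(defined, "cg_concept_ref")) {
    iri <- sct_iri(defined$sctid)
    label <- label %||% defined$term %||% iri
  } else {
    label <- label %||% (if (!is.null(defined)) defined$label else
      paste("expression", substr(cg_normal_form(serialize_cg(expr)), 1, 40)))
    iri <- paste0("SCTO_EXP_", gsub("[^A-Za-z0-9]+", "_", label))
  }
  ont <- ont_add_class(ont, iri, label,
                       "Class defined by a post-coordinated expression.")

  rendered <- render_cg_body(expr, pattern)
  ont$data_properties <- bind_rows(ont$data_properties,
                                   rendered$new_data_properties) |>
    distinct(.data$name, .keep_all = TRUE)
  kind <- if (expr$status == "equivalent") "equivalent" else "subclass"
  ont_add_axiom(ont, owl_axiom(kind, subject = iri, expr = rendered$expr))
}

cg_referenced_ids <- function(expr) {
  ids <- map_chr(expr$focus, "sctid")
  collect_attr <- function(a) {
    v <- a$value
    c(a$name$sctid,
      if (inherits(v, "cg_concept_ref")) v$sctid
      else if (inherits(v, "cg_expression")) cg_referenced_ids(v))
  }
  unique(c(ids,
           unlist(map(expr$ungrouped, collect_attr)),
           unlist(map(expr$groups, function(g) unlist(map(g, collect_attr))))))
}

render_cg_body <- function(expr, pattern) {
  new_props <- data_property_table()[0, ]
  render_attr <- function(a) {
    v <- a$value
    if (inherits(v, "cg_concrete_value")) {
      prop <- paste0(sct_iri(a$name$sctid), "_value")
      new_props <<- add_row(new_props,
        name = prop,
        definition = sprintf("Concrete value of attribute %s (expression-local).",
                             a$name$sctid),
        domain = sct_iri(SCT_ROOT),
        range = if (v$kind == "numeric") "xsd:decimal" else "xsd:string",
        functional = TRUE)
      return(o_dataval(prop, format(v$value, scientific = FALSE, trim = TRUE)))
    }
    filler <- if (inherits(v, "cg_concept_ref")) {
      o_ref(sct_iri(v$sctid))
    } else {
      inner <- render_cg_body(v, pattern)
      new_props <<- bind_rows(new_props, inner$new_data_properties)
      inner$expr
    }
    o_some("IsSourceOf", o_and(list(
      o_some("Relationship_destinationId", filler),
      o_some("Relationship_typeId", o_ref(sct_iri(a$name$sctid)))
    )))
  }
  parts <- c(
    map(expr$focus, function(r) o_ref(sct_iri(r$sctid))),
    map(expr$ungrouped, render_attr)
  )
  for (g in expr$groups) {
    inner <- map(g, function(a) {
      v <- a$value
      if (inherits(v, "cg_concrete_value")) {
        return(render_attr(a))
      }
      filler <- if (inherits(v, "cg_concept_ref")) {
        o_ref(sct_iri(v$sctid))
      } else {
        r <- render_cg_body(v, pattern)
        new_props <<- bind_rows(new_props, r$new_data_properties)
        r$expr
      }
      o_and(list(o_some("Relationship_destinationId", filler),
                 o_some("Relationship_typeId", o_ref(sct_iri(a$name$sctid)))))
    })
    if (pattern == "reified" && length(inner) > 1L) {
      first <- inner[[1L]]
      rest <- map(inner[-1L], function(x) {
        o_exactly(1L, "Grouped_Relations", x)
      })
      parts <- c(parts, list(o_some("IsSourceOf", o_and(c(list(first), rest)))))
    } else {
      parts <- c(parts, map(inner, function(x) {
        if (identical(x$variant, "dataval")) x else o_some("IsSourceOf", x)
      }))
    }
  }
  list(expr = o_and(parts), new_data_properties = distinct(new_props))
}

# ---- concept-model (SCM) rules ---------------------------------------------

#' Build a concept-model rule table
#'
#' Each rule states that an attribute applies to sources under a domain
#' hierarchy with values under one of the permitted value hierarchies (any
#' descendant-or-self of a permitted concept is permitted), and whether the
#' attribute may appear inside relationship groups.
#'
#' @param domain_hierarchy,attribute Character vectors of SCTIDs.
#' @param permitted List of character vectors (one per rule).
#' @param groupable Logical vector.
#' @return A tibble of class `scm_rules`.
#' @export
scm_rules <- function(domain_hierarchy, attribute, permitted, groupable = TRUE) {
  out <- tibble(domain_hierarchy = as.character(domain_hierarchy),
                attribute = as.character(attribute),
                permitted = map(permitted, as.character),
                groupable = rep_len(groupable, length(attribute)))
  class(out) <- c("scm_rules", class(out))
  out
}

#' Default concept-model rules for the fixture vocabulary
#'
#' A small rule table covering the attributes used by the worked examples:
#' finding-site and associated-morphology values must be body structures,
#' causative agents organisms/substances/objects, qualifier-style
#' attributes (episodicity, method, dose form, laterality) qualifier
#' values, procedure sites body structures, procedure devices physical
#' objects, and active ingredients substances.
#'
#' @return An `scm_rules` tibble.
#' @export
default_scm_rules <- function() {
  scm_rules(
    domain_hierarchy = c("404684003", "404684003", "404684003", "404684003",
                         "71388002", "71388002", "71388002",
                         "373873005", "373873005", "123037004"),
    attribute = c("363698007", "116676008", "246456000", "246075003",
                  "260686004", "405813007", "405815000",
                  "411116001", "127489000", "272741003"),
    permitted = list("123037004", "123037004", "362981000",
                     c("410607006", "105590001", "260787004"),
                     "362981000", "123037004", "260787004",
                     "362981000", "105590001", "362981000"),
    groupable = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                  FALSE)
  )
}

#' Validate attribute applications against concept-model rules
#'
#' Checks every attribute application in a compositional-grammar expression
#' (recursively, including groups and nested expressions) or in the active
#' non-IS_A rows of a snapshot. An application violates the model when no
#' rule for its attribute admits the source concept under its domain
#' hierarchy, or when its value is not a descendant-or-self of any
#' permitted value hierarchy. Attributes with no rule at all are not
#' checked (an empty rule table accepts everything). Violations are data,
#' not errors.
#'
#' @param target A `cg_expression` (or expression string) or an
#'   [rf2_snapshot()].
#' @param rules An [scm_rules()] table.
#' @param taxonomy A [taxonomy_index()] supplying the hierarchy.
#' @return Tibble of violations: `source`, `attribute`, `value`, `problem`
#'   (`"domain"` or `"range"`).
#' @export
scm_validate <- function(target, rules, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy_index"))
  apps <- if (inherits(target, "rf2_snapshot")) {
    rel <- filter(target$relationships,
                  .data$active == "1", .data$typeId != SCT_IS_A)
    tibble(source = map(rel$sourceId, identity),
           attribute = rel$typeId, value = rel$destinationId)
  } else {
    if (is.character(target)) target <- parse_cg(target)
    cg_applications(target)
  }
  if (nrow(apps) == 0 || nrow(rules) == 0) {
    return(tibble(source = character(), attribute = character(),
                  value = character(), problem = character()))
  }
  purrr::map_dfr(seq_len(nrow(apps)), function(i) {
    sources <- unlist(apps$source[i])
    attribute <- apps$attribute[i]
    value <- apps$value[i]
    cand <- rules[map_lgl(rules$attribute, function(a) {
      any(map_lgl(attribute, is_a_or_self, index = taxonomy, ancestor = a))
    }), , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    dom_ok <- map_lgl(cand$domain_hierarchy, function(d) {
      any(map_lgl(sources, is_a_or_self, index = taxonomy, ancestor = d))
    })
    if (!any(dom_ok)) {
      return(tibble(source = paste(sources, collapse = "+"),
                    attribute = attribute, value = value,
                    problem = "domain"))
    }
    if (is.na(value)) return(NULL)  # concrete values carry no hierarchy
    ok <- any(map_lgl(which(dom_ok), function(j) {
      any(map_lgl(cand$permitted[[j]], function(p) {
        is_a_or_self(taxonomy, value, p)
      }))
    }))
    if (!ok) {
      return(tibble(source = paste(sources, collapse = "+"),
                    attribute = attribute, value = value,
                    problem = "range"))
    }
    NULL
  })
}

# Flatten an expression into attribute applications: one row per attribute,
# with the focus concepts of its (possibly nested) expression as sources.
cg_applications <- function(expr) {
  sources <- list(map_chr(expr$focus, "sctid"))
  attrs <- c(expr$ungrouped, unlist(expr$groups, recursive = FALSE))
  rows <- purrr::map_dfr(attrs, function(a) {
    v <- a$value
    value <- if (inherits(v, "cg_concept_ref")) v$sctid
             else if (inherits(v, "cg_expression")) map_chr(v$focus, "sctid")[1]
             else NA_character_
    tibble(source = sources, attribute = a$name$sctid, value = value)
  })
  nested <- purrr::map_dfr(attrs, function(a) {
    if (inherits(a$value, "cg_expression")) cg_applications(a$value)
    else NULL
  })
  bind_rows(rows, nested)
}
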
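# RF2 snapshot store: the sole gateway between release files and the
# in-memory model. Snapshot tables are plain tibbles whose columns follow
# the RF2 Snapshot column order; all identifier-valued columns are kept as
# character vectors.

RF2_CONCEPT_COLS <- c("id", "effectiveTime", "active", "moduleId",
                      "definitionStatusId")
RF2_DESCRIPTION_COLS <- c("id", "effectiveTime", "active", "moduleId",
                          "conceptId", "languageCode", "typeId", "term",
                          "caseSignificanceId")
RF2_RELATIONSHIP_COLS <- c("id", "effectiveTime", "active", "moduleId",
                           "sourceId", "destinationId", "relationshipGroup",
                           "typeId", "characteristicTypeId", "modifierId")

#' Construct an RF2 snapshot from component tables
#'
#' An `rf2_snapshot` bundles the three Snapshot tables of an RF2 release --
#' concepts, descriptions, and relationships -- as tibbles with the standard
#' RF2 columns. Identifier columns are character (SCTIDs are digit strings
#' that overflow doubles); `relationshipGroup` is integer; `active` is kept
#' as the release's "0"/"1" flags so that a snapshot round-trips through
#' files byte-identically.
#'
#' @param concepts,descriptions,relationships Data frames with the RF2
#'   Snapshot columns for each table. Missing tables default to empty.
#' @param validate Run [validate_snapshot()] before returning?
#' @return An object of class `rf2_snapshot`: a list with elements
#'   `concepts`, `descriptions`, `relationships`.
#' @export
rf2_snapshot <- function(concepts = empty_concepts(),
                         descriptions = empty_descriptions(),
                         relationships = empty_relationships(),
                         validate = TRUE) {
  concepts <- coerce_rf2_table(concepts, RF2_CONCEPT_COLS, "Concept")
  descriptions <- coerce_rf2_table(descriptions, RF2_DESCRIPTION_COLS,
                                   "Description")
  relationships <- coerce_rf2_table(relationships, RF2_RELATIONSHIP_COLS,
                                    "Relationship")
  snap <- structure(
    list(concepts = concepts, descriptions = descriptions,
         relationships = relationships),
    class = "rf2_snapshot"
  )
  if (validate) validate_snapshot(snap)
  snap
}

empty_concepts <- function() {
  as_tibble(stats::setNames(rep(list(character()), 5), RF2_CONCEPT_COLS))
}
empty_descriptions <- function() {
  as_tibble(stats::setNames(rep(list(character()), 9), RF2_DESCRIPTION_COLS))
}
empty_relationships <- function() {
  tbl <- stats::setNames(rep(list(character()), 10), RF2_RELATIONSHIP_COLS)
  tbl$relationshipGroup <- integer()
  as_tibble(tbl)
}

coerce_rf2_table <- function(x, cols, table) {
  x <- as_tibble(x)
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s table is missing columns: %s", table,
                  paste(missing, collapse = ", ")))
  }
  x <- x[cols]
  for (col in setdiff(cols, "relationshipGroup")) {
    x[[col]] <- as.character(x[[col]])
  }
  if ("relationshipGroup" %in% cols) {
    x$relationshipGroup <- as.integer(x$relationshipGroup)
  }
  x
}

#' @export
print.rf2_snapshot <- function(x, ...) {
  cat(sprintf(
    "<rf2_snapshot> %d concepts, %d descriptions, %d relationships\n",
    nrow(x$concepts), nrow(x$descriptions), nrow(x$relationships)))
  invisible(x)
}

#' Validate an RF2 snapshot
#'
#' Checks structural invariants: identifiers are digit strings, concept ids
#' are unique, `definitionStatusId` is one of the two release values
#' (primitive or fully defined), descriptions and relationships reference
#' existing concepts, and IS_A rows are ungrouped (`relationshipGroup = 0`,
#' which the release format requires for the 116680003 relationship type).
#'
#' @param snapshot An [rf2_snapshot()].
#' @return The snapshot, invisibly. Errors with all problems on failure.
#' @export
validate_snapshot <- function(snapshot) {
  stopifnot(inherits(snapshot, "rf2_snapshot"))
  con <- snapshot$concepts
  des <- snapshot$descriptions
  rel <- snapshot$relationships
  problems <- character()

  for (tbl in list(con, des, rel)) {
    bad <- tbl$id[!is_sctid(tbl$id)]
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("non-SCTID id value(s): %s",
                                      paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  dup <- con$id[duplicated(con$id)]
  if (length(dup) > 0) {
    problems <- c(problems, sprintf("duplicate concept id(s): %s",
                                    paste(unique(dup), collapse = ", ")))
  }
  bad_status <- setdiff(unique(con$definitionStatusId),
                        c(SCT_PRIMITIVE, SCT_FULLY_DEFINED))
  if (length(bad_status) > 0) {
    problems <- c(problems, sprintf(
      "definitionStatusId must be %s (primitive) or %s (fully defined); found: %s",
      SCT_PRIMITIVE, SCT_FULLY_DEFINED, paste(bad_status, collapse = ", ")))
  }
  dangling_desc <- setdiff(des$conceptId, con$id)
  if (length(dangling_desc) > 0) {
    problems <- c(problems, sprintf(
      "description conceptId(s) not in Concept table: %s",
      paste(utils::head(dangling_desc, 5), collapse = ", ")))
  }
  dangling_rel <- setdiff(c(rel$sourceId, rel$destinationId), con$id)
  if (length(dangling_rel) > 0) {
    problems <- c(problems, sprintf(
      "relationship source/destination id(s) not in Concept table: %s",
      paste(utils::head(dangling_rel, 5), collapse = ", ")))
  }
  grouped_isa <- rel$id[rel$typeId == SCT_IS_A & rel$relationshipGroup != 0L]
  if (length(grouped_isa) > 0) {
    problems <- c(problems, sprintf(
      "IS_A relationships must have relationshipGroup 0 (row id(s): %s)",
      paste(utils::head(grouped_isa, 5), collapse = ", ")))
  }
  if (any(is.na(rel$relationshipGroup)) ||
      any(rel$relationshipGroup < 0L, na.rm = TRUE)) {
    problems <- c(problems, "relationshipGroup must be a non-negative integer")
  }
  if (length(problems) > 0) {
    abort(c("invalid RF2 snapshot", problems))
  }
  invisible(snapshot)
}

#' Read an RF2 snapshot from tab-separated files
#'
#' Reads the three Snapshot tables from tab-separated UTF-8 files with a
#' header row, as shipped in RF2 releases. Inactive rows are parsed and
#' retained (the `active` flag is preserved data used for backward
#' compatibility); they are only excluded later when the taxonomy index is
#' built.
#'
#' @param concept_path,description_path,relationship_path Paths to the
#'   Concept, Description, and Relationship snapshot files.
#' @param validate Run [validate_snapshot()] on the result?
#' @return An [rf2_snapshot()].
#' @export
read_snapshot <- function(concept_path, description_path, relationship_path,
                          validate = TRUE) {
  rf2_snapshot(
    concepts = read_rf2_table(concept_path, RF2_CONCEPT_COLS, "Concept"),
    descriptions = read_rf2_table(description_path, RF2_DESCRIPTION_COLS,
                                  "Description"),
    relationships = read_rf2_table(relationship_path, RF2_RELATIONSHIP_COLS,
                                   "Relationship"),
    validate = validate
  )
}

read_rf2_table <- function(path, cols, table) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", table, path))
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    quote = "", na = character(), progress = FALSE,
    locale = readr::locale(encoding = "UTF-8")
  )
  if (!identical(names(tbl), cols)) {
    abort(sprintf("%s file %s: expected columns [%s], found [%s]",
                  table, path, paste(cols, collapse = ", "),
                  paste(names(tbl), collapse = ", ")))
  }
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(sprintf("%s file %s: malformed row at line %d (%s)",
                  table, path, prob$row[1] + 1L, prob$expected[1]))
  }
  coerce_rf2_table(tbl, cols, table)
}

#' Write an RF2 snapshot to tab-separated files
#'
#' Writes the three Snapshot tables as tab-separated UTF-8 files with header
#' rows. Rows are sorted by id so that two writes of equal snapshots are
#' byte-identical, and `read_snapshot(write_snapshot(s))` reproduces `s`.
#'
#' @param snapshot An [rf2_snapshot()]; it is validated first.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_snapshot <- function(snapshot, dir) {
  validate_snapshot(snapshot)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    concept = file.path(dir, "sct2_Concept_Snapshot.txt"),
    description = file.path(dir, "sct2_Description_Snapshot.txt"),
    relationship = file.path(dir, "sct2_Relationship_Snapshot.txt")
  )
  write_rf2_table(arrange(snapshot$concepts, .data$id), paths[["concept"]])
  write_rf2_table(arrange(snapshot$descriptions, .data$id),
                  paths[["description"]])
  write_rf2_table(arrange(snapshot$relationships, .data$id),
                  paths[["relationship"]])
  invisible(paths)
}

write_rf2_table <- function(tbl, path) {
  tbl <- mutate(tbl, across(everything(), as.character))
  lines <- c(paste(names(tbl), collapse = "\t"),
             if (nrow(tbl) > 0) do.call(paste, c(unname(as.list(tbl)), sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Build a taxonomy index from a snapshot
#'
#' Extracts the concept hierarchy from the active IS_A rows (typeId
#' 116680003) and memoizes ancestor closures. Inactive rows never contribute
#' edges unless `include_inactive = TRUE`; the release keeps them only for
#' backward compatibility and the hierarchy of record is the active one.
#'
#' @param snapshot An [rf2_snapshot()].
#' @param include_inactive Also use inactive IS_A rows as edges?
#' @return A `taxonomy_index` with the child-to-parents map and closure
#'   accessors; errors (naming one cycle) if the IS_A graph is cyclic.
#' @export
taxonomy_index <- function(snapshot, include_inactive = FALSE) {
  stopifnot(inherits(snapshot, "rf2_snapshot"))
  rel <- snapshot$relationships
  isa <- rel[rel$typeId == SCT_IS_A &
               (include_inactive | rel$active == "1"), , drop = FALSE]
  parents <- split(isa$destinationId, isa$sourceId)
  parents <- lapply(parents, function(p) sort(unique(p)))
  idx <- structure(
    list(parents = parents,
         concepts = sort(unique(snapshot$concepts$id)),
         cache = new.env(parent = emptyenv())),
    class = "taxonomy_index"
  )
  cyc <- find_isa_cycle(parents)
  if (!is.null(cyc)) {
    abort(sprintf("IS_A graph is cyclic: %s", paste(cyc, collapse = " -> ")))
  }
  idx
}

# Depth-first search for a cycle in the child -> parents map; returns one
# witnessed cycle as a vector of ids, or NULL.
find_isa_cycle <- function(parents) {
  state <- new.env(parent = emptyenv()) # 1 = in progress, 2 = done
  path <- character()
  found <- NULL
  visit <- function(node) {
    if (!is.null(found)) return()
    st <- state[[node]] %||% 0L
    if (st == 2L) return()
    if (st == 1L) {
      start <- match(node, path)
      found <<- c(path[start:length(path)], node)
      return()
    }
    state[[node]] <- 1L
    path <<- c(path, node)
    for (p in parents[[node]] %||% character()) visit(p)
    path <<- path[-length(path)]
    state[[node]] <- 2L
  }
  for (n in names(parents)) visit(n)
  found
}

#' @export
print.taxonomy_index <- function(x, ...) {
  cat(sprintf("<taxonomy_index> %d concepts, %d with parents\n",
              length(x$concepts), length(x$parents)))
  invisible(x)
}

#' Strict ancestors of a concept
#'
#' @param index A [taxonomy_index()].
#' @param id SCTID of the concept.
#' @return Sorted character vector of all strict ancestors (empty for roots
#'   and for ids absent from the index).
#' @export
ancestors <- function(index, id) {
  stopifnot(inherits(index, "taxonomy_index"))
  id <- as.character(id)
  cached <- index$cache[[id]]
  if (!is.null(cached)) return(cached)
  seen <- character()
  frontier <- index$parents[[id]] %||% character()
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(frontier, function(p) index$parents[[p]]),
                    use.names = FALSE)),
      seen)
  }
  res <- sort(seen)
  index$cache[[id]] <- res
  res
}

#' Strict descendants of a concept
#' @inheritParams ancestors
#' @return Sorted character vector of all strict descendants.
#' @export
descendants <- function(index, id) {
  stopifnot(inherits(index, "taxonomy_index"))
  id <- as.character(id)
  all_ids <- union(index$concepts, names(index$parents))
  sort(all_ids[map_lgl(all_ids, function(c) id %in% ancestors(index, c))])
}

#' Reflexive subsumption test on the concept hierarchy
#'
#' @inheritParams ancestors
#' @param ancestor Candidate ancestor SCTID.
#' @return `TRUE` iff `id` equals `ancestor` or `ancestor` is a strict
#'   ancestor of `id`.
#' @export
is_a_or_self <- function(index, id, ancestor) {
  id <- as.character(id)
  ancestor <- as.character(ancestor)
  identical(id, ancestor) || ancestor %in% ancestors(index, id)
}
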
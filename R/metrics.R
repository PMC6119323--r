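# Ontology and release statistics. Hierarchy metrics are computed over the
# named-parent edges of the class axioms (a subclass or equivalence axiom
# contributes one edge per named class at the top of its right-hand
# conjunction); depth is counted in edges from a parentless class, and
# sibling/children averages exclude classes without the respective feature.

# Named parent edges (child, parent) implied by the class axioms.
ontology_edges <- function(ont) {
  rows <- purrr::map_dfr(ont$class_axioms, function(ax) {
    if (!(ax$kind %in% c("subclass", "equivalent")) || is.null(ax$expr)) {
      return(NULL)
    }
    members <- if (ax$expr$variant == "and") ax$expr$members else list(ax$expr)
    parents <- map_chr(keep(members, function(m) m$variant == "ref"), "iri")
    if (length(parents) == 0) return(NULL)
    tibble(child = ax$subject, parent = parents)
  })
  distinct(rows)
}

#' Structural metrics of an ontology
#'
#' Computes the summary metrics of the artifact: class, axiom, and property
#' counts, hierarchy shape (parents, children, siblings, depth), and
#' annotation count. Formulas: siblings of a class are the other direct
#' subclasses of any of its parents; children/sibling averages run over the
#' classes that have children/parents respectively; depth is the longest
#' chain of parent edges from a parentless class, in edges; annotations
#' counts annotation assertions (one label and one textual definition per
#' class and property); `axioms` counts logical axioms (class axioms plus
#' property domain, range, inverse, characteristic, and functionality
#' axioms), and `axioms_with_annotations` adds the annotation assertions.
#'
#' @param ont An `scto_ontology`.
#' @return A one-row tibble of class `metric_report`.
#' @export
ontology_metrics <- function(ont) {
  stopifnot(inherits(ont, "scto_ontology"))
  edges <- ontology_edges(ont)
  classes <- ont$classes$iri
  n_parents <- table(factor(edges$child, levels = classes))
  n_children <- table(factor(edges$parent, levels = classes))

  siblings <- map_int(classes, function(c) {
    parents <- edges$parent[edges$child == c]
    if (length(parents) == 0) return(NA_integer_)
    length(setdiff(unique(edges$child[edges$parent %in% parents]), c))
  })

  depth <- longest_depths(edges, classes)

  op <- ont$object_properties
  dp <- ont$data_properties
  property_axioms <- 2L * nrow(op) + 2L * nrow(dp) +          # domains/ranges
    sum(nzchar(op$inverse_of) & op$name < op$inverse_of) +
    sum(nzchar(op$characteristics)) + sum(dp$functional)
  annotations <- 2L * (length(classes) + nrow(op) + nrow(dp))
  logical_axioms <- length(ont$class_axioms) + property_axioms

  out <- tibble(
    classes = length(classes),
    axioms = logical_axioms,
    axioms_with_annotations = logical_axioms + annotations,
    object_properties = nrow(op),
    data_properties = nrow(dp),
    max_parents = max(c(0L, as.integer(n_parents))),
    avg_siblings = mean(siblings, na.rm = TRUE),
    max_children = max(c(0L, as.integer(n_children))),
    avg_children = mean(as.integer(n_children)[as.integer(n_children) > 0]),
    classes_gt25_children = sum(as.integer(n_children) > 25L),
    single_child_classes = sum(as.integer(n_children) == 1L),
    max_siblings = max(c(0L, siblings), na.rm = TRUE),
    subclass_axioms = sum(map_chr(ont$class_axioms, "kind") == "subclass"),
    annotations = annotations,
    max_depth = depth
  )
  class(out) <- c("metric_report", class(out))
  out
}

# Longest path (in edges) from a parentless class, over the parent DAG.
longest_depths <- function(edges, classes) {
  if (nrow(edges) == 0) return(0L)
  memo <- new.env(parent = emptyenv())
  depth_of <- function(c) {
    hit <- memo[[c]]
    if (!is.null(hit)) return(hit)
    memo[[c]] <- 0L  # cycle guard
    parents <- edges$parent[edges$child == c]
    d <- if (length(parents) == 0) 0L else 1L + max(map_int(parents, depth_of))
    memo[[c]] <- d
    d
  }
  max(map_int(unique(c(classes, edges$child)), depth_of))
}

#' Relationship-group statistics of a snapshot
#'
#' Over the active non-IS_A rows: the percentage carrying a non-zero
#' relationship group, and, among those grouped rows, the percentage share
#' of each attribute (`typeId`).
#'
#' @param snapshot An [rf2_snapshot()].
#' @return A `group_stats` list: `grouped_pct` (0 with a warning when the
#'   snapshot has no non-IS_A rows), `n_non_isa`, `n_grouped`, and
#'   `by_attribute` (tibble `typeId`, `n`, `share_pct`).
#' @export
rf2_group_stats <- function(snapshot) {
  stopifnot(inherits(snapshot, "rf2_snapshot"))
  rel <- filter(snapshot$relationships,
                .data$active == "1", .data$typeId != SCT_IS_A)
  if (nrow(rel) == 0) {
    warn("snapshot has no active non-IS_A relationships; grouped share is 0")
    out <- list(grouped_pct = 0, n_non_isa = 0L, n_grouped = 0L,
                by_attribute = tibble(typeId = character(), n = integer(),
                                      share_pct = numeric()))
    return(structure(out, class = "group_stats"))
  }
  grouped <- filter(rel, .data$relationshipGroup != 0L)
  by_attr <- grouped |>
    count(.data$typeId, name = "n") |>
    mutate(share_pct = 100 * .data$n / max(1L, nrow(grouped))) |>
    arrange(desc(.data$n), .data$typeId)
  structure(list(
    grouped_pct = 100 * nrow(grouped) / nrow(rel),
    n_non_isa = nrow(rel),
    n_grouped = nrow(grouped),
    by_attribute = by_attr
  ), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> %d/%d active non-IS_A rows grouped (%.2f%%)\n",
              x$n_grouped, x$n_non_isa, x$grouped_pct))
  if (nrow(x$by_attribute) > 0) print(x$by_attribute)
  invisible(x)
}
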
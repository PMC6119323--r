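# Broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col coord_flip labs
#' @export
ggplot2::autoplot

#' Tidy the class axioms of an ontology
#'
#' @param x An `scto_ontology`.
#' @param ... Unused.
#' @return Tibble with one row per class axiom: `subject`, `kind`, and the
#'   axiom rendered in functional syntax.
#' @export
tidy.scto_ontology <- function(x, ...) {
  purrr::map_dfr(x$class_axioms, function(ax) {
    tibble(
      subject = ax$subject %||% NA_character_,
      kind = ax$kind,
      axiom = switch(ax$kind,
        subclass = sprintf("SubClassOf(:%s %s)", ax$subject,
                           cexpr_functional(ax$expr)),
        equivalent = sprintf("EquivalentClasses(:%s %s)", ax$subject,
                             cexpr_functional(ax$expr)),
        disjoint = sprintf("DisjointClasses(%s)",
                           paste0(":", sort(ax$members), collapse = " ")))
    )
  })
}

#' One-row summary of an ontology
#'
#' @param x An `scto_ontology`.
#' @param ... Unused.
#' @return The [ontology_metrics()] report.
#' @export
glance.scto_ontology <- function(x, ...) ontology_metrics(x)

#' Tidy a subsumption relation
#'
#' @param x A `subsumption_relation`.
#' @param ... Unused.
#' @return Tibble with columns `sub`, `super`.
#' @export
tidy.subsumption_relation <- function(x, ...) x$pairs

#' One-row summary of an RF2 snapshot
#'
#' @param x An [rf2_snapshot()].
#' @param ... Unused.
#' @return Tibble of table sizes and activity counts.
#' @export
glance.rf2_snapshot <- function(x, ...) {
  rel <- x$relationships
  tibble(
    concepts = nrow(x$concepts),
    descriptions = nrow(x$descriptions),
    relationships = nrow(rel),
    active_is_a = sum(rel$typeId == SCT_IS_A & rel$active == "1"),
    non_is_a = sum(rel$typeId != SCT_IS_A),
    grouped = sum(rel$typeId != SCT_IS_A & rel$relationshipGroup != 0L)
  )
}

#' Plot ontology metrics
#'
#' @param object A `metric_report` from [ontology_metrics()].
#' @param ... Unused.
#' @return A ggplot bar chart of the metric values.
#' @export
autoplot.metric_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = dplyr::everything(),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = stats::reorder(.data$metric, .data$value),
                   y = .data$value)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "value", title = "Ontology metrics")
}

#' Plot relationship-group attribute shares
#'
#' @param object A `group_stats` from [rf2_group_stats()].
#' @param ... Unused.
#' @return A ggplot bar chart of the per-attribute shares of grouped rows.
#' @export
autoplot.group_stats <- function(object, ...) {
  ggplot(object$by_attribute,
         aes(x = stats::reorder(.data$typeId, .data$share_pct),
             y = .data$share_pct)) +
    geom_col() +
    coord_flip() +
    labs(x = "attribute (typeId)", y = "share of grouped rows (%)",
         title = sprintf("%.1f%% of non-IS_A rows are grouped",
                         object$grouped_pct))
}
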
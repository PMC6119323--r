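# OWL 2 serialization: functional-style syntax as the canonical,
# byte-deterministic interchange format, and Manchester syntax for human
# reading. Two profiles: "dl" emits the axioms exactly as modeled
# (including qualified cardinality and ONLY restrictions); "el_safe"
# degrades them to the lightweight profile -- cardinality linkages become
# plain existentials and ONLY restrictions are dropped with a warning.

#' Emitter profile
#'
#' @param profile `"dl"` (axioms as modeled) or `"el_safe"` (no
#'   cardinality, universal, or inverse constructs; offending restrictions
#'   are degraded or dropped with a warning).
#' @param syntax `"functional"` or `"manchester"`.
#' @param include_annotations Emit label and textual-definition
#'   annotations?
#' @return An `emitter_profile`.
#' @export
emitter_profile <- function(profile = c("dl", "el_safe"),
                            syntax = c("functional", "manchester"),
                            include_annotations = TRUE) {
  structure(list(profile = match.arg(profile), syntax = match.arg(syntax),
                 include_annotations = include_annotations),
            class = "emitter_profile")
}

# Degrade a class expression to the lightweight profile.
el_safe_cexpr <- function(e, warnings) {
  switch(e$variant,
    ref = , dataval = list(expr = e, warnings = warnings),
    and = {
      out <- list()
      for (m in e$members) {
        r <- el_safe_cexpr(m, warnings)
        warnings <- r$warnings
        if (!is.null(r$expr)) out <- c(out, list(r$expr))
      }
      list(expr = if (length(out) == 0) NULL else o_and(out),
           warnings = warnings)
    },
    some = {
      r <- el_safe_cexpr(e$expr, warnings)
      list(expr = if (is.null(r$expr)) NULL else o_some(e$prop, r$expr),
           warnings = r$warnings)
    },
    exactly = {
      r <- el_safe_cexpr(e$expr, warnings)
      list(expr = if (is.null(r$expr)) NULL else o_some(e$prop, r$expr),
           warnings = c(r$warnings, sprintf(
             "qualified cardinality on %s degraded to an existential", e$prop)))
    },
    only = list(expr = NULL,
                warnings = c(warnings, sprintf(
                  "universal (ONLY) restriction on %s dropped", e$prop)))
  )
}

cexpr_functional <- function(e) {
  switch(e$variant,
    ref = paste0(":", e$iri),
    and = paste0("ObjectIntersectionOf(",
                 paste(map_chr(e$members, cexpr_functional), collapse = " "),
                 ")"),
    some = paste0("ObjectSomeValuesFrom(:", e$prop, " ",
                  cexpr_functional(e$expr), ")"),
    only = paste0("ObjectAllValuesFrom(:", e$prop, " ",
                  cexpr_functional(e$expr), ")"),
    exactly = paste0("ObjectExactCardinality(", e$n, " :", e$prop, " ",
                     cexpr_functional(e$expr), ")"),
    dataval = paste0("DataHasValue(:", e$prop, " \"", e$value, "\")")
  )
}

cexpr_manchester <- function(e, top = FALSE) {
  wrap <- function(s) if (top) s else paste0("(", s, ")")
  switch(e$variant,
    ref = paste0("'", e$iri, "'"),
    and = wrap(paste(map_chr(e$members, cexpr_manchester), collapse = " and ")),
    some = wrap(paste0(e$prop, " some ", cexpr_manchester(e$expr))),
    only = wrap(paste0(e$prop, " only ", cexpr_manchester(e$expr))),
    exactly = wrap(paste0(e$prop, " exactly ", e$n, " ",
                          cexpr_manchester(e$expr))),
    dataval = wrap(paste0(e$prop, " value \"", e$value, "\""))
  )
}

#' Serialize an ontology to OWL 2
#'
#' A pure function of the ontology and profile: declarations are sorted,
#' then axioms by subject, so two emissions of equal ontologies are
#' byte-identical. Functional-style syntax is the canonical interchange
#' format; Manchester output mirrors the `Class:` / `SubClassOf:` /
#' `EquivalentTo:` block style used when the schema is presented by hand.
#'
#' @param ont An `scto_ontology`.
#' @param prof An [emitter_profile()].
#' @return A single string (the document).
#' @export
emit <- function(ont, prof = emitter_profile()) {
  stopifnot(inherits(ont, "scto_ontology"), inherits(prof, "emitter_profile"))
  axioms <- ont$class_axioms
  if (prof$profile == "el_safe") {
    warnings <- character()
    axioms <- compact(map(axioms, function(ax) {
      if (is.null(ax$expr)) return(ax)
      r <- el_safe_cexpr(ax$expr, character())
      warnings <<- c(warnings, r$warnings)
      if (is.null(r$expr)) return(NULL)
      ax$expr <- r$expr
      ax
    }))
    if (length(warnings) > 0) {
      warn(c("axioms degraded for the el_safe profile",
             unique(warnings)))
    }
  }
  if (prof$syntax == "functional") {
    emit_functional(ont, axioms, prof)
  } else {
    emit_manchester(ont, axioms, prof)
  }
}

annotation_rows <- function(ont) {
  bind_rows(
    transmute(ont$classes, subject = .data$iri, label = .data$label,
              definition = .data$definition),
    transmute(ont$object_properties, subject = .data$name,
              label = .data$name, definition = .data$definition),
    transmute(ont$data_properties, subject = .data$name,
              label = .data$name, definition = .data$definition)
  ) |> arrange(.data$subject)
}

esc <- function(x) gsub("\"", "\\\\\"", x)

emit_functional <- function(ont, axioms, prof) {
  base <- ont$config$iri_base
  lines <- c(
    sprintf("Prefix(:=<%s>)", base),
    "Prefix(owl:=<http://www.w3.org/2002/07/owl#>)",
    "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
    "Prefix(xsd:=<http://www.w3.org/2001/XMLSchema#>)",
    sprintf("Ontology(<%s>", sub("#$", "", base))
  )
  cls <- sort(ont$classes$iri, method = "radix")
  lines <- c(lines, sprintf("Declaration(Class(:%s))", cls))
  ops <- sort(ont$object_properties$name, method = "radix")
  lines <- c(lines, sprintf("Declaration(ObjectProperty(:%s))", ops))
  dps <- sort(ont$data_properties$name, method = "radix")
  lines <- c(lines, sprintf("Declaration(DataProperty(:%s))", dps))
  inds <- sort(ont$individuals$id, method = "radix")
  lines <- c(lines, sprintf("Declaration(NamedIndividual(:%s))", inds))

  op <- arrange(ont$object_properties, .data$name)
  for (i in seq_len(nrow(op))) {
    r <- op[i, ]
    if (nzchar(r$inverse_of) && r$name < r$inverse_of) {
      lines <- c(lines, sprintf("InverseObjectProperties(:%s :%s)",
                                r$name, r$inverse_of))
    }
    if (nzchar(r$characteristics) && grepl("Symmetric", r$characteristics)) {
      lines <- c(lines, sprintf("SymmetricObjectProperty(:%s)", r$name))
    }
    lines <- c(lines,
               sprintf("ObjectPropertyDomain(:%s :%s)", r$name, r$domain),
               sprintf("ObjectPropertyRange(:%s :%s)", r$name, r$range))
  }
  dp <- arrange(ont$data_properties, .data$name)
  for (i in seq_len(nrow(dp))) {
    r <- dp[i, ]
    if (r$functional) {
      lines <- c(lines, sprintf("FunctionalDataProperty(:%s)", r$name))
    }
    lines <- c(lines,
               sprintf("DataPropertyDomain(:%s :%s)", r$name, r$domain),
               sprintf("DataPropertyRange(:%s %s)", r$name, r$range))
  }

  ax_lines <- map_chr(axioms, function(ax) {
    switch(ax$kind,
      subclass = sprintf("SubClassOf(:%s %s)", ax$subject,
                         cexpr_functional(ax$expr)),
      equivalent = sprintf("EquivalentClasses(:%s %s)", ax$subject,
                           cexpr_functional(ax$expr)),
      disjoint = sprintf("DisjointClasses(%s)",
                         paste0(":", sort(ax$members), collapse = " "))
    )
  })
  lines <- c(lines, sort(ax_lines, method = "radix"))

  if (nrow(ont$assertions) > 0) {
    a <- arrange(ont$assertions, .data$subject, .data$property, .data$object)
    lines <- c(lines, sprintf("ObjectPropertyAssertion(:%s :%s :%s)",
                              a$property, a$subject, a$object))
  }
  if (nrow(ont$grouped_relations) > 0) {
    g <- arrange(ont$grouped_relations, .data$r1, .data$r2)
    lines <- c(lines, sprintf(
      "ObjectPropertyAssertion(:Grouped_Relations :%s :%s)", g$r1, g$r2))
  }
  if (nrow(ont$data_assertions) > 0) {
    d <- arrange(ont$data_assertions, .data$subject, .data$property,
                 .data$value)
    lines <- c(lines, sprintf(
      "DataPropertyAssertion(:%s :%s \"%s\"^^%s)",
      d$property, d$subject, esc(d$value), d$datatype))
  }

  if (prof$include_annotations) {
    ann <- annotation_rows(ont)
    lines <- c(lines,
      sprintf("AnnotationAssertion(rdfs:label :%s \"%s\")",
              ann$subject, esc(ann$label)),
      sprintf("AnnotationAssertion(rdfs:comment :%s \"%s\")",
              ann$subject, esc(ann$definition)))
  }
  paste0(paste(c(lines, ")"), collapse = "\n"), "\n")
}

emit_manchester <- function(ont, axioms, prof) {
  lines <- c(sprintf("Prefix: : <%s>", ont$config$iri_base), "")
  by_subject <- split(axioms, map_chr(axioms, function(ax) ax$subject %||% ""))
  for (iri in sort(ont$classes$iri, method = "radix")) {
    row <- ont$classes[ont$classes$iri == iri, ]
    lines <- c(lines, sprintf("Class: '%s'", iri))
    if (prof$include_annotations) {
      lines <- c(lines, sprintf("    Annotations: rdfs:label \"%s\"",
                                esc(row$label)))
    }
    for (ax in by_subject[[iri]] %||% list()) {
      header <- switch(ax$kind, subclass = "SubClassOf:",
                       equivalent = "EquivalentTo:", next)
      lines <- c(lines, paste0("    ", header, " ",
                               cexpr_manchester(ax$expr, top = TRUE)))
    }
    lines <- c(lines, "")
  }
  disjoints <- keep(axioms, function(ax) ax$kind == "disjoint")
  for (ax in disjoints) {
    lines <- c(lines, paste0("DisjointClasses: ",
                             paste0("'", sort(ax$members), "'",
                                    collapse = ", ")),
               "")
  }
  op <- arrange(ont$object_properties, .data$name)
  for (i in seq_len(nrow(op))) {
    r <- op[i, ]
    lines <- c(lines, sprintf("ObjectProperty: %s", r$name),
               sprintf("    Domain: '%s'", r$domain),
               sprintf("    Range: '%s'", r$range))
    if (nzchar(r$inverse_of)) {
      lines <- c(lines, sprintf("    InverseOf: %s", r$inverse_of))
    }
    if (nzchar(r$characteristics)) {
      lines <- c(lines, sprintf("    Characteristics: %s", r$characteristics))
    }
    lines <- c(lines, "")
  }
  dp <- arrange(ont$data_properties, .data$name)
  for (i in seq_len(nrow(dp))) {
    r <- dp[i, ]
    lines <- c(lines, sprintf("DataProperty: %s", r$name),
               sprintf("    Domain: '%s'", r$domain),
               sprintf("    Range: %s", r$range))
    if (r$functional) lines <- c(lines, "    Characteristics: Functional")
    lines <- c(lines, "")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Count declarations and axioms in an emitted document
#'
#' Scans a functional-syntax document produced by [emit()] and counts the
#' declared classes, object properties, data properties, named
#' individuals, annotation assertions, and class axioms (subclass,
#' equivalence, disjointness).
#'
#' @param doc Document string (or path to one).
#' @return One-row tibble of counts.
#' @export
declaration_census <- function(doc) {
  if (length(doc) == 1L && !grepl("\n", doc) && file.exists(doc)) {
    doc <- paste(readLines(doc, warn = FALSE), collapse = "\n")
  }
  if (!grepl("^Prefix\\(", doc)) {
    abort("declaration_census expects a functional-syntax document from emit()")
  }
  lines <- strsplit(doc, "\n", fixed = TRUE)[[1]]
  count <- function(pattern) sum(grepl(pattern, lines))
  tibble(
    classes = count("^Declaration\\(Class\\("),
    object_properties = count("^Declaration\\(ObjectProperty\\("),
    data_properties = count("^Declaration\\(DataProperty\\("),
    individuals = count("^Declaration\\(NamedIndividual\\("),
    class_axioms = count("^(SubClassOf|EquivalentClasses|DisjointClasses)\\("),
    subclass_axioms = count("^SubClassOf\\("),
    annotations = count("^AnnotationAssertion\\(")
  )
}
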
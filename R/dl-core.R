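# EL++ description-logic core: the construct subset used by the clinical
# terminology (top, bottom, concept names, conjunction, existential
# restriction) extended with role groups and opaque concrete restrictions,
# TBox axioms, canonicalization, and a finite-model semantics used as a
# brute-force oracle. Constructors outside the subset (negation,
# disjunction, universal quantification as a class constructor, inverse
# roles) deliberately do not exist at the type level.

#' DL expression constructors
#'
#' Build expressions of the supported description-logic subset:
#' `dl_top()` and `dl_bottom()` for the universal and empty class,
#' `dl_name(sctid)` for concept names, `dl_and(...)` for conjunction,
#' `dl_some(role, filler)` for existential restriction,
#' `dl_group(...)` for a role group over existential members, and
#' `dl_value(role, value, kind)` for an opaque concrete-value restriction
#' (equal values compare equal; no concrete-domain reasoning).
#'
#' @param sctid Concept name (digit string).
#' @param role Role name (digit string, or the reserved group role).
#' @param filler A DL expression.
#' @param ... Member expressions (conjuncts or group members).
#' @param value Numeric or character concrete value.
#' @param kind `"numeric"` or `"string"`.
#' @return A `dl_expr` object.
#' @name dl-constructors
NULL

dl_expr <- function(variant, fields) {
  structure(c(list(variant = variant), fields), class = "dl_expr")
}

#' @rdname dl-constructors
#' @export
dl_top <- function() dl_expr("top", list())

#' @rdname dl-constructors
#' @export
dl_bottom <- function() dl_expr("bottom", list())

#' @rdname dl-constructors
#' @export
dl_name <- function(sctid) {
  assert_sctid(sctid, "concept name")
  dl_expr("name", list(sctid = sctid))
}

#' @rdname dl-constructors
#' @export
dl_and <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1L]]) &&
      !inherits(members[[1L]], "dl_expr")) {
    members <- members[[1L]]
  }
  stopifnot(all(map_lgl(members, inherits, "dl_expr")))
  if (length(members) == 0) abort("conjunction needs at least one member")
  dl_expr("and", list(members = members))
}

#' @rdname dl-constructors
#' @export
dl_some <- function(role, filler) {
  if (!identical(role, RG_ROLE)) assert_sctid(role, "role name")
  stopifnot(inherits(filler, "dl_expr"))
  dl_expr("some", list(role = role, filler = filler))
}

#' @rdname dl-constructors
#' @export
dl_group <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1L]]) &&
      !inherits(members[[1L]], "dl_expr")) {
    members <- members[[1L]]
  }
  ok <- map_lgl(members, function(m) {
    inherits(m, "dl_expr") && m$variant %in% c("some", "value")
  })
  if (length(members) == 0 || !all(ok)) {
    abort("a role group needs at least one existential or concrete member")
  }
  dl_expr("group", list(members = members))
}

#' @rdname dl-constructors
#' @export
dl_value <- function(role, value, kind = if (is.numeric(value)) "numeric" else "string") {
  assert_sctid(role, "role name")
  stopifnot(kind %in% c("numeric", "string"))
  dl_expr("value", list(role = role, value = value, kind = kind))
}

#' @export
print.dl_expr <- function(x, ...) {
  cat("<dl_expr>", dl_format(x), "\n")
  invisible(x)
}

#' Render a DL expression with standard notation
#'
#' @param expr A `dl_expr`.
#' @return A string using the conventional symbols for conjunction,
#'   existential restriction, and brace-delimited role groups.
#' @export
dl_format <- function(expr) {
  switch(expr$variant,
    top = "⊤",
    bottom = "⊥",
    name = expr$sctid,
    and = paste(map_chr(expr$members, function(m) {
      s <- dl_format(m)
      if (m$variant == "and") paste0("(", s, ")") else s
    }), collapse = " ⊓ "),
    some = paste0("∃", expr$role, ".",
                  if (expr$filler$variant %in% c("and", "some"))
                    paste0("(", dl_format(expr$filler), ")")
                  else dl_format(expr$filler)),
    group = paste0("{", paste(map_chr(expr$members, dl_format),
                              collapse = " ⊓ "), "}"),
    value = paste0("∃", expr$role, ".",
                   if (expr$kind == "numeric")
                     paste0("#", format(expr$value, scientific = FALSE, trim = TRUE))
                   else paste0("\"", expr$value, "\""))
  )
}

# Stable total-order serialization key; canonical ordering sorts on it.
dl_key <- function(expr) {
  switch(expr$variant,
    top = "~top",
    bottom = "~bottom",
    name = paste0("c:", expr$sctid),
    and = paste0("and(", paste(map_chr(expr$members, dl_key), collapse = ","), ")"),
    some = paste0("some(", expr$role, ",", dl_key(expr$filler), ")"),
    group = paste0("rg(", paste(map_chr(expr$members, dl_key), collapse = ","), ")"),
    value = paste0("val(", expr$role, ",", expr$kind, ":",
                   format(expr$value, scientific = FALSE, trim = TRUE), ")")
  )
}

#' Structural equality of DL expressions up to canonical form
#' @param a,b `dl_expr` objects.
#' @return `TRUE` iff the canonical forms are identical.
#' @export
dl_equal <- function(a, b) {
  identical(dl_key(canonical_form(a)), dl_key(canonical_form(b)))
}

#' Canonical form of a DL expression
#'
#' Flattens nested conjunctions, canonicalizes fillers and group members
#' recursively, removes duplicate conjuncts, drops redundant top conjuncts,
#' sorts members by a stable serialization key, and unwraps single-member
#' conjunctions. Idempotent and insensitive to member order.
#'
#' @param expr A `dl_expr`.
#' @return The canonical `dl_expr`.
#' @export
canonical_form <- function(expr) {
  stopifnot(inherits(expr, "dl_expr"))
  switch(expr$variant,
    top = expr,
    bottom = expr,
    name = expr,
    value = expr,
    some = dl_some(expr$role, canonical_form(expr$filler)),
    group = {
      members <- map(expr$members, canonical_form)
      keys <- map_chr(members, dl_key)
      ord <- order(keys, method = "radix")
      dl_group(members[ord][!duplicated(keys[ord])])
    },
    and = {
      members <- flatten_and(map(expr$members, canonical_form))
      members <- discard(members, function(m) m$variant == "top")
      if (length(members) == 0) return(dl_top())
      keys <- map_chr(members, dl_key)
      ord <- order(keys, method = "radix")
      members <- members[ord][!duplicated(keys[ord])]
      if (length(members) == 1L) members[[1L]] else dl_and(members)
    }
  )
}

flatten_and <- function(members) {
  out <- list()
  for (m in members) {
    if (m$variant == "and") out <- c(out, m$members) else out <- c(out, list(m))
  }
  out
}

# All concept and role names mentioned in an expression.
dl_signature <- function(expr) {
  switch(expr$variant,
    top = ,
    bottom = list(concepts = character(), roles = character()),
    name = list(concepts = expr$sctid, roles = character()),
    value = list(concepts = character(), roles = expr$role),
    some = {
      s <- dl_signature(expr$filler)
      list(concepts = s$concepts, roles = union(expr$role, s$roles))
    },
    and = ,
    group = {
      parts <- map(expr$members, dl_signature)
      list(concepts = unique(unlist(map(parts, "concepts"))),
           roles = unique(c(if (expr$variant == "group") RG_ROLE,
                            unlist(map(parts, "roles")))))
    }
  )
}

# Replace role groups by existentials over the reserved group role; the
# whole reasoner operates on desugared expressions.
dl_desugar <- function(expr) {
  switch(expr$variant,
    top = ,
    bottom = ,
    name = ,
    value = expr,
    some = dl_some(expr$role, dl_desugar(expr$filler)),
    and = dl_and(map(expr$members, dl_desugar)),
    group = {
      members <- map(expr$members, dl_desugar)
      filler <- if (length(members) == 1L) members[[1L]] else dl_and(members)
      dl_some(RG_ROLE, filler)
    }
  )
}

# ---- TBox ------------------------------------------------------------------

#' TBox axiom constructors
#'
#' `ax_sub(lhs, rhs)` asserts a general class inclusion, `ax_equiv(lhs,
#' rhs)` a class equivalence (the pair of inclusions), `ax_role_sub(sub,
#' super)` a role inclusion, `ax_domain(role, class)` and `ax_range(role,
#' class)` property domain/range restrictions, and `ax_disjoint(a, b)` class
#' disjointness (the inclusion of the conjunction in the empty class).
#'
#' @param lhs,rhs,a,b `dl_expr` objects (names may be given as strings).
#' @param sub,super,role Role names.
#' @param class A `dl_expr` (or concept-name string).
#' @return A `dl_axiom`.
#' @name dl-axioms
NULL

as_dl <- function(x) if (is.character(x)) dl_name(x) else x

dl_axiom <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "dl_axiom")
}

#' @rdname dl-axioms
#' @export
ax_sub <- function(lhs, rhs) {
  dl_axiom("sub", list(lhs = as_dl(lhs), rhs = as_dl(rhs)))
}

#' @rdname dl-axioms
#' @export
ax_equiv <- function(lhs, rhs) {
  dl_axiom("equiv", list(lhs = as_dl(lhs), rhs = as_dl(rhs)))
}

#' @rdname dl-axioms
#' @export
ax_role_sub <- function(sub, super) {
  dl_axiom("role_sub", list(sub = sub, super = super))
}

#' @rdname dl-axioms
#' @export
ax_domain <- function(role, class) {
  dl_axiom("domain", list(role = role, class = as_dl(class)))
}

#' @rdname dl-axioms
#' @export
ax_range <- function(role, class) {
  dl_axiom("range", list(role = role, class = as_dl(class)))
}

#' @rdname dl-axioms
#' @export
ax_disjoint <- function(a, b) {
  dl_axiom("disjoint", list(a = as_dl(a), b = as_dl(b)))
}

#' Construct a TBox
#'
#' @param axioms List of [dl-axioms] objects.
#' @return A `dl_tbox` holding the axioms and the signature (concept and
#'   role names mentioned anywhere).
#' @export
dl_tbox <- function(axioms = list()) {
  stopifnot(all(map_lgl(axioms, inherits, "dl_axiom")))
  concepts <- character()
  roles <- character()
  for (ax in axioms) {
    exprs <- switch(ax$kind,
      sub = , equiv = list(ax$lhs, ax$rhs),
      disjoint = list(ax$a, ax$b),
      domain = , range = list(ax$class),
      role_sub = list()
    )
    for (e in exprs) {
      s <- dl_signature(e)
      concepts <- union(concepts, s$concepts)
      roles <- union(roles, s$roles)
    }
    roles <- union(roles, switch(ax$kind,
      role_sub = c(ax$sub, ax$super),
      domain = , range = ax$role,
      character()))
  }
  structure(list(axioms = axioms,
                 concepts = sort(concepts, method = "radix"),
                 roles = sort(roles, method = "radix")),
            class = "dl_tbox")
}

#' @export
print.dl_tbox <- function(x, ...) {
  cat(sprintf("<dl_tbox> %d axioms over %d concept and %d role names\n",
              length(x$axioms), length(x$concepts), length(x$roles)))
  invisible(x)
}

#' Build a TBox from an RF2 snapshot
#'
#' Active IS_A rows become name-to-name inclusions; active non-IS_A rows
#' become existential restrictions on their source concept, bundled into
#' role groups when they share a non-zero relationship group. A concept
#' whose `definitionStatusId` marks it fully defined contributes an
#' equivalence over the conjunction of its parents and restrictions;
#' primitive concepts contribute inclusions only.
#'
#' @param snapshot An [rf2_snapshot()].
#' @return A `dl_tbox`.
#' @export
snapshot_tbox <- function(snapshot) {
  stopifnot(inherits(snapshot, "rf2_snapshot"))
  rel <- filter(snapshot$relationships, .data$active == "1")
  isa <- filter(rel, .data$typeId == SCT_IS_A)
  attr_rel <- filter(rel, .data$typeId != SCT_IS_A)
  defined <- snapshot$concepts$id[
    snapshot$concepts$definitionStatusId == SCT_FULLY_DEFINED]

  axioms <- list()
  for (cid in sort(unique(c(isa$sourceId, attr_rel$sourceId)), method = "radix")) {
    parents <- sort(isa$destinationId[isa$sourceId == cid], method = "radix")
    rows <- attr_rel[attr_rel$sourceId == cid, , drop = FALSE]
    parts <- map(parents, dl_name)
    ungrouped <- rows[rows$relationshipGroup == 0L, , drop = FALSE]
    parts <- c(parts, map(seq_len(nrow(ungrouped)), function(i) {
      dl_some(ungrouped$typeId[i], dl_name(ungrouped$destinationId[i]))
    }))
    for (g in sort(unique(rows$relationshipGroup[rows$relationshipGroup > 0L]))) {
      grp <- rows[rows$relationshipGroup == g, , drop = FALSE]
      parts <- c(parts, list(dl_group(map(seq_len(nrow(grp)), function(i) {
        dl_some(grp$typeId[i], dl_name(grp$destinationId[i]))
      }))))
    }
    if (length(parts) == 0) next
    rhs <- canonical_form(dl_and(parts))
    axioms <- c(axioms, list(
      if (cid %in% defined) ax_equiv(dl_name(cid), rhs)
      else ax_sub(dl_name(cid), rhs)))
  }
  dl_tbox(axioms)
}

# ---- CG <-> DL translation -------------------------------------------------

#' Translate a compositional-grammar expression to DL
#'
#' Focus concepts become concept names, ungrouped refinements existential
#' restrictions, attribute groups role groups, nested expression values
#' conjunction fillers, and concrete values opaque concrete restrictions.
#' The definition status travels alongside as the axiom kind (equivalence
#' for `===`, inclusion for `<<<`).
#'
#' @param expr A `cg_expression`.
#' @param taxonomy Optional [taxonomy_index()]; when given, every referenced
#'   concept must be known to it.
#' @return List with `expr` (canonical `dl_expr`) and `kind`
#'   (`"equivalent"` or `"subtype"`).
#' @export
cg_to_dl <- function(expr, taxonomy = NULL) {
  stopifnot(inherits(expr, "cg_expression"))
  dl <- canonical_form(cg_body_to_dl(expr))
  if (!is.null(taxonomy)) {
    known <- union(taxonomy$concepts, names(taxonomy$parents))
    missing <- setdiff(dl_signature(dl)$concepts, known)
    if (length(missing) > 0) {
      abort(sprintf("unknown concept id(s): %s", paste(missing, collapse = ", ")))
    }
  }
  list(expr = dl, kind = expr$status)
}

cg_body_to_dl <- function(expr) {
  parts <- c(
    map(expr$focus, function(r) dl_name(r$sctid)),
    map(expr$ungrouped, cg_attr_to_dl),
    map(expr$groups, function(g) dl_group(map(g, cg_attr_to_dl)))
  )
  if (length(parts) == 1L) parts[[1L]] else dl_and(parts)
}

cg_attr_to_dl <- function(attr) {
  v <- attr$value
  if (inherits(v, "cg_concrete_value")) {
    dl_value(attr$name$sctid, v$value, v$kind)
  } else if (inherits(v, "cg_expression")) {
    dl_some(attr$name$sctid, cg_body_to_dl(v))
  } else {
    dl_some(attr$name$sctid, dl_name(v$sctid))
  }
}

#' Translate a DL expression back to compositional grammar
#'
#' Inverse of [cg_to_dl()] for CG-expressible shapes: role groups may occur
#' only at the top conjunction level, and fillers must themselves be
#' CG-expressible. `cg_to_dl(dl_to_cg(e))` reproduces the canonical `e`.
#'
#' @param expr A `dl_expr`.
#' @param kind Axiom kind carried onto the expression status.
#' @return A `cg_expression`.
#' @export
dl_to_cg <- function(expr, kind = "equivalent") {
  stopifnot(inherits(expr, "dl_expr"))
  body <- dl_body_to_cg(canonical_form(expr))
  new_cg_expression(kind, body$focus, body$ungrouped, body$groups)
}

dl_body_to_cg <- function(expr) {
  members <- if (expr$variant == "and") expr$members else list(expr)
  focus <- list()
  ungrouped <- list()
  groups <- list()
  for (m in members) {
    switch(m$variant,
      name = { focus[[length(focus) + 1L]] <- cg_concept_ref(m$sctid) },
      some = { ungrouped[[length(ungrouped) + 1L]] <- dl_some_to_attr(m) },
      value = { ungrouped[[length(ungrouped) + 1L]] <- dl_value_to_attr(m) },
      group = {
        groups[[length(groups) + 1L]] <-
          structure(map(m$members, function(g) {
            if (g$variant == "value") dl_value_to_attr(g) else dl_some_to_attr(g)
          }), class = "cg_group")
      },
      abort(sprintf("DL construct '%s' has no compositional-grammar rendering",
                    m$variant))
    )
  }
  list(focus = focus, ungrouped = ungrouped, groups = groups)
}

dl_some_to_attr <- function(m) {
  filler <- m$filler
  value <- if (filler$variant == "name") {
    cg_concept_ref(filler$sctid)
  } else {
    body <- dl_body_to_cg(filler)
    if (length(body$focus) == 0) {
      abort("existential filler without a concept name has no compositional-grammar rendering")
    }
    new_cg_expression("equivalent", body$focus, body$ungrouped, body$groups)
  }
  cg_attribute(cg_concept_ref(m$role), value)
}

dl_value_to_attr <- function(m) {
  cg_attribute(cg_concept_ref(m$role), cg_concrete_value(m$kind, m$value))
}

# ---- finite-model semantics ------------------------------------------------

#' Construct a finite interpretation
#'
#' A finite model: a domain of individuals, class extensions, and role
#' extensions, used as the brute-force semantic oracle for the reasoner.
#' Concrete restrictions are interpreted as atomic classes keyed by their
#' role/value token (exact-value semantics).
#'
#' @param domain Character vector of individuals.
#' @param classes Named list: concept name -> subset of `domain`.
#' @param roles Named list: role name -> two-column matrix (or data frame)
#'   of ordered pairs over `domain`.
#' @return A `dl_interpretation`.
#' @export
dl_interpretation <- function(domain, classes = list(), roles = list()) {
  domain <- as.character(domain)
  classes <- map(classes, function(x) intersect(as.character(x), domain))
  roles <- map(roles, function(m) {
    m <- matrix(as.character(m), ncol = 2)
    m[m[, 1] %in% domain & m[, 2] %in% domain, , drop = FALSE]
  })
  structure(list(domain = domain, classes = classes, roles = roles),
            class = "dl_interpretation")
}

#' @export
print.dl_interpretation <- function(x, ...) {
  cat(sprintf("<dl_interpretation> |domain| = %d, %d classes, %d roles\n",
              length(x$domain), length(x$classes), length(x$roles)))
  invisible(x)
}

value_token <- function(expr) {
  paste0("value:", expr$role, ":", expr$kind, ":",
         format(expr$value, scientific = FALSE, trim = TRUE))
}

#' Extension of a DL expression in an interpretation
#'
#' Evaluates the standard set semantics: the universal class denotes the
#' whole domain, conjunction intersects, and an existential restriction
#' collects the individuals with an appropriate role successor. Role groups
#' are evaluated as existentials over the reserved group role with the
#' member conjunction as filler. Names missing from the interpretation have
#' empty extensions.
#'
#' @param interp A [dl_interpretation()].
#' @param expr A `dl_expr`.
#' @return Character vector of individuals.
#' @export
extension <- function(interp, expr) {
  stopifnot(inherits(interp, "dl_interpretation"), inherits(expr, "dl_expr"))
  switch(expr$variant,
    top = interp$domain,
    bottom = character(),
    name = interp$classes[[expr$sctid]] %||% character(),
    value = interp$classes[[value_token(expr)]] %||% character(),
    and = Reduce(intersect, map(expr$members, extension, interp = interp)),
    group = extension(interp, dl_desugar(expr)),
    some = {
      pairs <- interp$roles[[expr$role]]
      if (is.null(pairs) || nrow(pairs) == 0) return(character())
      filler_ext <- extension(interp, expr$filler)
      unique(pairs[pairs[, 2] %in% filler_ext, 1])
    }
  )
}

# Does one axiom hold in the interpretation?
axiom_holds <- function(interp, ax) {
  switch(ax$kind,
    sub = length(setdiff(extension(interp, ax$lhs),
                         extension(interp, ax$rhs))) == 0,
    equiv = setequal(extension(interp, ax$lhs), extension(interp, ax$rhs)),
    disjoint = length(intersect(extension(interp, ax$a),
                                extension(interp, ax$b))) == 0,
    role_sub = {
      sub <- interp$roles[[ax$sub]]
      sup <- interp$roles[[ax$super]]
      if (is.null(sub) || nrow(sub) == 0) TRUE
      else if (is.null(sup)) FALSE
      else all(paste(sub[, 1], sub[, 2]) %in% paste(sup[, 1], sup[, 2]))
    },
    domain = {
      pairs <- interp$roles[[ax$role]]
      if (is.null(pairs) || nrow(pairs) == 0) TRUE
      else all(unique(pairs[, 1]) %in% extension(interp, ax$class))
    },
    range = {
      pairs <- interp$roles[[ax$role]]
      if (is.null(pairs) || nrow(pairs) == 0) TRUE
      else all(unique(pairs[, 2]) %in% extension(interp, ax$class))
    }
  )
}

#' Is an interpretation a model of a TBox?
#'
#' @param interp A [dl_interpretation()].
#' @param tbox A [dl_tbox()].
#' @return `TRUE` iff the semantic condition of every axiom holds.
#' @export
is_model <- function(interp, tbox) {
  stopifnot(inherits(tbox, "dl_tbox"))
  all(map_lgl(tbox$axioms, axiom_holds, interp = interp))
}
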
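# Bounded finite-model search: an independent soundness probe for the
# classifier. A candidate structure is grown into a model by monotone
# repair (memberships and role edges are only ever added), so the search
# terminates on a genuine model or reports inconsistency; it never uses
# the completion calculus.

# Mutable model-construction state over at most max_domain individuals.
new_model_builder <- function(max_domain) {
  st <- new.env(parent = emptyenv())
  st$max_domain <- max_domain
  st$nodes <- character()
  st$node_of <- new.env(parent = emptyenv()) # expression key -> node
  st$classes <- list()  # name -> character vector of nodes
  st$edges <- list()    # role -> list(from = chr, to = chr)
  st$inconsistent <- FALSE
  st
}

mb_new_node <- function(st, key = NULL) {
  if (!is.null(key)) {
    hit <- st$node_of[[key]]
    if (!is.null(hit)) return(hit)
  }
  if (length(st$nodes) >= st$max_domain) {
    # domain exhausted: fold further individuals onto the last node; the
    # repair loop still ends on a genuine (if coarser) model
    node <- st$nodes[length(st$nodes)]
  } else {
    node <- paste0("x", length(st$nodes) + 1L)
    st$nodes <- c(st$nodes, node)
  }
  if (!is.null(key)) st$node_of[[key]] <- node
  node
}

mb_add_class <- function(st, node, name) {
  cur <- st$classes[[name]]
  if (node %in% cur) return(FALSE)
  st$classes[[name]] <- c(cur, node)
  TRUE
}

mb_add_edge <- function(st, from, to, role, sup_roles) {
  changed <- FALSE
  for (s in sup_roles[[role]] %||% role) {
    e <- st$edges[[s]] %||% list(from = character(), to = character())
    if (!any(e$from == from & e$to == to)) {
      st$edges[[s]] <- list(from = c(e$from, from), to = c(e$to, to))
      changed <- TRUE
    }
  }
  changed
}

mb_interp <- function(st) {
  dl_interpretation(
    domain = st$nodes,
    classes = st$classes,
    roles = map(st$edges, function(e) cbind(e$from, e$to))
  )
}

# Make `node` satisfy `expr` (desugared, value-tokenized). Returns TRUE if
# anything was added.
mb_enforce <- function(st, node, expr, sup_roles) {
  switch(expr$variant,
    top = FALSE,
    bottom = { st$inconsistent <- TRUE; FALSE },
    name = mb_add_class(st, node, expr$sctid),
    and = any(map_lgl(expr$members, function(m)
      mb_enforce(st, node, m, sup_roles))),
    some = {
      filler <- expr$filler
      succ <- mb_new_node(st, key = dl_key(canonical_form(filler)))
      changed <- mb_add_edge(st, node, succ, expr$role, sup_roles)
      mb_enforce(st, succ, filler, sup_roles) || changed
    }
  )
}

# Role hierarchy closure for the builder (role -> all super roles incl self).
tbox_role_closure <- function(tbox) {
  roles <- tbox$roles
  sup <- stats::setNames(as.list(roles), roles)
  pairs <- keep(tbox$axioms, function(ax) ax$kind == "role_sub")
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (ax in pairs) {
      add <- setdiff(sup[[ax$super]] %||% ax$super, sup[[ax$sub]])
      if (length(add) > 0) {
        sup[[ax$sub]] <- c(sup[[ax$sub]] %||% ax$sub, add)
        changed <- TRUE
      }
    }
  }
  sup
}

# Repair the structure until every axiom holds (or inconsistency).
mb_close <- function(st, tbox, sup_roles) {
  prep_ax <- function(e) prep_expr(e)
  repeat {
    if (st$inconsistent) return(invisible(st))
    changed <- FALSE
    # group composition RG o r <= r on the structure itself, mirroring the
    # classifier's reading of role groups
    rg <- st$edges[[RG_ROLE]]
    if (!is.null(rg)) {
      for (i in seq_along(rg$from)) {
        for (r in setdiff(names(st$edges), RG_ROLE)) {
          e <- st$edges[[r]]
          for (z in e$to[e$from == rg$to[i]]) {
            if (mb_add_edge(st, rg$from[i], z, r, sup_roles)) changed <- TRUE
          }
        }
      }
    }
    interp <- mb_interp(st)
    for (ax in tbox$axioms) {
      targets <- switch(ax$kind,
        sub = list(list(lhs = prep_ax(ax$lhs), rhs = prep_ax(ax$rhs))),
        equiv = list(list(lhs = prep_ax(ax$lhs), rhs = prep_ax(ax$rhs)),
                     list(lhs = prep_ax(ax$rhs), rhs = prep_ax(ax$lhs))),
        disjoint = list(list(lhs = dl_and(list(prep_ax(ax$a), prep_ax(ax$b))),
                             rhs = dl_bottom())),
        domain = list(list(lhs = dl_some(ax$role, dl_top()),
                           rhs = prep_ax(ax$class))),
        range = NULL,
        role_sub = NULL
      )
      if (ax$kind == "range") {
        e <- st$edges[[ax$role]]
        if (!is.null(e)) {
          for (to in unique(e$to)) {
            if (mb_enforce(st, to, prep_ax(ax$class), sup_roles)) changed <- TRUE
          }
        }
        next
      }
      if (is.null(targets)) next  # role_sub handled on edge insertion
      for (t in targets) {
        holders <- extension(interp, t$lhs)
        sat <- extension(interp, t$rhs)
        for (x in setdiff(holders, sat)) {
          if (mb_enforce(st, x, t$rhs, sup_roles)) changed <- TRUE
          if (st$inconsistent) return(invisible(st))
        }
      }
    }
    if (changed) { interp <- mb_interp(st); next }
    if (is_model(mb_interp(st), tbox)) break
    # nothing to repair but still not a model can only mean stale caches;
    # loop once more (extension is recomputed above)
    break
  }
  invisible(st)
}

#' Search for a bounded counter-model to a subsumption
#'
#' Builds the least model containing a witness of `a` over at most
#' `max_domain` individuals (one per distinct existential filler; extra
#' individuals fold onto the last one) and closes it under the TBox axioms
#' by monotone repair. If the witness fails to satisfy `b` in the result,
#' that interpretation refutes the subsumption; otherwise no counter-model
#' within the bound was found. The search is deterministic.
#'
#' @param tbox A [dl_tbox()].
#' @param a,b `dl_expr` objects (names accepted as strings).
#' @param max_domain Domain bound, at most 8 (the search cost grows quickly).
#' @return A [dl_interpretation()] with some individual in the extension of
#'   `a` but not of `b`, or `NULL` when none exists within the bound.
#' @export
find_countermodel <- function(tbox, a, b, max_domain = 6L) {
  stopifnot(inherits(tbox, "dl_tbox"), max_domain >= 1, max_domain <= 8)
  a <- prep_expr(canonical_form(as_dl(a)))
  b <- prep_expr(canonical_form(as_dl(b)))
  st <- new_model_builder(max_domain)
  sup_roles <- tbox_role_closure(tbox)
  root <- mb_new_node(st, key = "~root")
  mb_enforce(st, root, a, sup_roles)
  mb_close(st, tbox, sup_roles)
  if (st$inconsistent) return(NULL)  # a is unsatisfiable: subsumption holds
  interp <- mb_interp(st)
  if (root %in% extension(interp, b)) return(NULL)
  if (!is_model(interp, tbox)) return(NULL)  # defensive; repair should converge
  interp
}

#' Generate a random finite model of a TBox
#'
#' Starts from seeded random class memberships and role edges over a fixed
#' domain and repairs the structure into a model by monotone completion
#' (the all-empty structure is always a model, so repair cannot diverge;
#' if disjointness makes the random start inconsistent, the start is
#' resampled with fewer random facts).
#'
#' @param tbox A [dl_tbox()].
#' @param domain_size Number of individuals.
#' @param seed Integer seed.
#' @param density Probability of each random membership/edge.
#' @return A [dl_interpretation()] that [is_model()] of `tbox`.
#' @export
random_model <- function(tbox, domain_size = 5L, seed = 1L, density = 0.2) {
  stopifnot(inherits(tbox, "dl_tbox"))
  withr::with_seed(seed, {
    sup_roles <- tbox_role_closure(tbox)
    for (attempt in seq_len(10L)) {
      st <- new_model_builder(domain_size)
      for (i in seq_len(domain_size)) mb_new_node(st)
      for (nm in tbox$concepts) {
        hit <- stats::runif(domain_size) < density
        for (x in st$nodes[hit]) mb_add_class(st, x, nm)
      }
      for (r in setdiff(tbox$roles, RG_ROLE)) {
        for (f in st$nodes) for (t in st$nodes) {
          if (stats::runif(1) < density / domain_size) {
            mb_add_edge(st, f, t, r, sup_roles)
          }
        }
      }
      mb_close(st, tbox, sup_roles)
      if (!st$inconsistent) return(mb_interp(st))
      density <- density / 2
    }
    # disjointness kept firing: fall back to the empty (always valid) model
    st <- new_model_builder(domain_size)
    for (i in seq_len(domain_size)) mb_new_node(st)
    mb_close(st, tbox, sup_roles)
    mb_interp(st)
  })
}
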
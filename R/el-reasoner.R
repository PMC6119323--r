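# EL++ reasoner: completion-rule saturation over normalized axioms.
# Role groups are desugared to existentials over the reserved group role
# before reasoning, so one calculus decides plain and grouped subsumption
# alike; concrete restrictions are opaque atoms (equal values compare
# equal). The naive fixpoint oracle and the bounded finite-model search
# live in separate code paths so they can cross-check the classifier.

TOP_ATOM <- "⊤"
BOT_ATOM <- "⊥"

# Internal atom constructor that bypasses the SCTID check (fresh names and
# value tokens are not digit strings).
atom_expr <- function(name) dl_expr("name", list(sctid = name))

# Desugar groups and replace concrete restrictions by their atomic tokens.
prep_expr <- function(expr) {
  expr <- dl_desugar(expr)
  replace_values <- function(e) {
    switch(e$variant,
      value = atom_expr(value_token(e)),
      and = dl_and(map(e$members, replace_values)),
      some = dl_some(e$role, replace_values(e$filler)),
      e
    )
  }
  replace_values(expr)
}

is_atomic <- function(e) e$variant %in% c("name", "top", "bottom")
atom_of <- function(e) {
  switch(e$variant, name = e$sctid, top = TOP_ATOM, bottom = BOT_ATOM)
}

# ---- normalization ---------------------------------------------------------

# Normal forms: gci1 A one B, gci2 A1 and A2 one B, gci3 A one some(r, B),
# gci4 some(r, A) one B, role inclusions, and role ranges -- all over atoms.
new_normalizer <- function(prefix = "__n") {
  st <- new.env(parent = emptyenv())
  st$counter <- 0L
  st$gci1 <- list(a = character(), b = character())
  st$gci2 <- list(a1 = character(), a2 = character(), b = character())
  st$gci3 <- list(a = character(), r = character(), b = character())
  st$gci4 <- list(r = character(), a = character(), b = character())
  st$role_sub <- list(sub = character(), super = character())
  st$ranges <- list(r = character(), b = character())
  st$prefix <- prefix
  st
}

fresh_atom <- function(st) {
  st$counter <- st$counter + 1L
  paste0(st$prefix, st$counter)
}

emit1 <- function(st, a, b) {
  st$gci1$a <- c(st$gci1$a, a); st$gci1$b <- c(st$gci1$b, b)
}
emit2 <- function(st, a1, a2, b) {
  st$gci2$a1 <- c(st$gci2$a1, a1); st$gci2$a2 <- c(st$gci2$a2, a2)
  st$gci2$b <- c(st$gci2$b, b)
}
emit3 <- function(st, a, r, b) {
  st$gci3$a <- c(st$gci3$a, a); st$gci3$r <- c(st$gci3$r, r)
  st$gci3$b <- c(st$gci3$b, b)
}
emit4 <- function(st, r, a, b) {
  st$gci4$r <- c(st$gci4$r, r); st$gci4$a <- c(st$gci4$a, a)
  st$gci4$b <- c(st$gci4$b, b)
}

# Reduce an expression to an atom, emitting definitional inclusions in the
# requested direction(s). `need` is "lhs" (atom must be entailed by the
# expression), "rhs" (atom must entail it), or "both".
atomize <- function(st, e, need) {
  if (is_atomic(e)) return(atom_of(e))
  a <- fresh_atom(st)
  if (need %in% c("lhs", "both")) norm_sub(st, e, atom_expr(a))
  if (need %in% c("rhs", "both")) norm_sub(st, atom_expr(a), e)
  a
}

norm_sub <- function(st, lhs, rhs) {
  if (lhs$variant == "group" || rhs$variant == "group") {
    abort("role groups must be desugared before normalization")
  }
  if (lhs$variant == "value" || rhs$variant == "value") {
    abort("concrete restrictions must be tokenized before normalization")
  }
  if (!is_atomic(lhs) && !is_atomic(rhs)) {
    mid <- fresh_atom(st)
    norm_sub(st, lhs, atom_expr(mid))
    norm_sub(st, atom_expr(mid), rhs)
    return(invisible())
  }
  if (is_atomic(lhs)) {
    a <- atom_of(lhs)
    switch(rhs$variant,
      name = , top = , bottom = emit1(st, a, atom_of(rhs)),
      and = for (m in rhs$members) norm_sub(st, lhs, m),
      some = {
        # B <= some(r, C^) becomes B <= some(r, A) with A <= C^
        filler <- if (is_atomic(rhs$filler)) atom_of(rhs$filler)
                  else atomize(st, rhs$filler, "rhs")
        emit3(st, a, rhs$role, filler)
      }
    )
    return(invisible())
  }
  # lhs complex, rhs atomic
  b <- atom_of(rhs)
  switch(lhs$variant,
    and = {
      # complex conjuncts C^ on the left become C^ <= A
      atoms <- map_chr(lhs$members, function(m) {
        if (is_atomic(m)) atom_of(m) else atomize(st, m, "lhs")
      })
      if (length(atoms) == 1L) {
        emit1(st, atoms, b)
      } else {
        acc <- atoms[1L]
        for (i in seq(2L, length(atoms))) {
          nxt <- if (i == length(atoms)) b else fresh_atom(st)
          emit2(st, acc, atoms[i], nxt)
          acc <- nxt
        }
      }
    },
    some = {
      # some(r, C^) <= B becomes some(r, A) <= B with C^ <= A
      filler <- if (is_atomic(lhs$filler)) atom_of(lhs$filler)
                else atomize(st, lhs$filler, "lhs")
      emit4(st, lhs$role, filler, b)
    }
  )
  invisible()
}

normalize_axioms <- function(axioms, st = new_normalizer()) {
  for (ax in axioms) {
    switch(ax$kind,
      sub = norm_sub(st, prep_expr(ax$lhs), prep_expr(ax$rhs)),
      equiv = {
        l <- prep_expr(ax$lhs); r <- prep_expr(ax$rhs)
        norm_sub(st, l, r)
        norm_sub(st, r, l)
      },
      disjoint = norm_sub(st, dl_and(list(prep_expr(ax$a), prep_expr(ax$b))),
                          dl_bottom()),
      domain = norm_sub(st, dl_some(ax$role, dl_top()), prep_expr(ax$class)),
      range = {
        # the successor atom entails the (possibly complex) range class
        cls <- prep_expr(ax$class)
        b <- if (is_atomic(cls)) atom_of(cls) else atomize(st, cls, "rhs")
        st$ranges$r <- c(st$ranges$r, ax$role)
        st$ranges$b <- c(st$ranges$b, b)
      },
      role_sub = {
        st$role_sub$sub <- c(st$role_sub$sub, ax$sub)
        st$role_sub$super <- c(st$role_sub$super, ax$super)
      },
      abort(sprintf("unsupported axiom kind '%s'", ax$kind))
    )
  }
  st
}

norm_atoms <- function(st) {
  unique(c(TOP_ATOM, BOT_ATOM,
           st$gci1$a, st$gci1$b, st$gci2$a1, st$gci2$a2, st$gci2$b,
           st$gci3$a, st$gci3$b, st$gci4$a, st$gci4$b, st$ranges$b))
}

norm_roles <- function(st) {
  unique(c(st$gci3$r, st$gci4$r, st$role_sub$sub, st$role_sub$super,
           st$ranges$r))
}

# Reflexive-transitive closure of the role hierarchy: named list
# role -> super-roles (including itself).
role_closure <- function(st, roles) {
  sup <- stats::setNames(as.list(roles), roles)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(st$role_sub$sub)) {
      r <- st$role_sub$sub[i]; s <- st$role_sub$super[i]
      add <- setdiff(sup[[s]], sup[[r]])
      if (length(add) > 0) { sup[[r]] <- c(sup[[r]], add); changed <- TRUE }
    }
  }
  sup
}

# ---- completion-rule saturation --------------------------------------------

# Saturate the normalized axiom set. Returns list(S = named list of
# subsumer sets per atom, atoms, roles).
saturate <- function(st, seed_atoms = character()) {
  atoms <- unique(c(norm_atoms(st), seed_atoms))
  roles <- norm_roles(st)
  sup_roles <- role_closure(st, roles)
  range_by_role <- split(st$ranges$b, st$ranges$r)

  S <- new.env(parent = emptyenv())
  for (a in atoms) S[[a]] <- c(a, TOP_ATOM)
  Rfrom <- stats::setNames(lapply(roles, function(r) character()), roles)
  Rto <- Rfrom

  add_S <- function(c, xs) {
    add <- setdiff(xs, S[[c]])
    if (length(add) == 0) return(FALSE)
    S[[c]] <- c(S[[c]], add)
    TRUE
  }
  add_edge <- function(from, to, r) {
    # close under the role hierarchy and apply range restrictions on entry
    changed <- FALSE
    for (s in sup_roles[[r]]) {
      key <- paste0(from, "\r", to)
      existing <- paste0(Rfrom[[s]], "\r", Rto[[s]])
      if (!(key %in% existing)) {
        Rfrom[[s]] <<- c(Rfrom[[s]], from)
        Rto[[s]] <<- c(Rto[[s]], to)
        changed <- TRUE
        rb <- range_by_role[[s]]
        if (!is.null(rb)) changed <- add_S(to, rb) || changed
      }
    }
    changed
  }

  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (c in atoms) {
      sc <- S[[c]]
      # CR1: A in S(C), A <= B  ==>  B in S(C)
      hit <- st$gci1$a %in% sc
      if (any(hit)) changed <- add_S(c, st$gci1$b[hit]) || changed
      # CR2: A1, A2 in S(C), A1 n A2 <= B  ==>  B in S(C)
      hit <- st$gci2$a1 %in% sc & st$gci2$a2 %in% sc
      if (any(hit)) changed <- add_S(c, st$gci2$b[hit]) || changed
      # CR3: A in S(C), A <= some(r, B)  ==>  (C, B) in R(r)
      hit <- which(st$gci3$a %in% sc)
      for (i in hit) {
        changed <- add_edge(c, st$gci3$b[i], st$gci3$r[i]) || changed
      }
    }
    # CR4: (C, D) in R(r), A in S(D), some(r, A) <= B  ==>  B in S(C)
    for (r in roles) {
      from <- Rfrom[[r]]; to <- Rto[[r]]
      if (length(from) == 0) next
      idx <- which(st$gci4$r == r)
      for (i in idx) {
        hit <- map_lgl(to, function(d) st$gci4$a[i] %in% S[[d]])
        if (any(hit)) {
          for (c in unique(from[hit])) {
            changed <- add_S(c, st$gci4$b[i]) || changed
          }
        }
      }
      # bottom propagation: an edge into an unsatisfiable atom makes the
      # source unsatisfiable
      hit <- map_lgl(to, function(d) BOT_ATOM %in% S[[d]])
      if (any(hit)) {
        for (c in unique(from[hit])) {
          changed <- add_S(c, BOT_ATOM) || changed
        }
      }
    }
    # group composition RG o r <= r: an attribute inside a role group is
    # still an attribute of the source (validates the redundancy rule that
    # absorbs an ungrouped restriction into a group)
    if (RG_ROLE %in% roles) {
      rg_from <- Rfrom[[RG_ROLE]]; rg_to <- Rto[[RG_ROLE]]
      for (i in seq_along(rg_from)) {
        for (r in setdiff(roles, RG_ROLE)) {
          succ <- Rto[[r]][Rfrom[[r]] == rg_to[i]]
          for (z in succ) {
            changed <- add_edge(rg_from[i], z, r) || changed
          }
        }
      }
    }
  }
  list(S = S, atoms = atoms, roles = roles)
}

subsumption_relation <- function(pairs, names) {
  structure(list(pairs = pairs, names = names,
                 keys = paste0(pairs$sub, "\r", pairs$super)),
            class = "subsumption_relation")
}

#' @export
print.subsumption_relation <- function(x, ...) {
  cat(sprintf("<subsumption_relation> %d pairs over %d names\n",
              nrow(x$pairs), length(x$names)))
  invisible(x)
}

#' Look up a pair in a subsumption relation
#' @param rel A relation from [classify()] or [naive_closure()].
#' @param sub,super Concept names.
#' @return `TRUE` iff `sub` is subsumed by `super`.
#' @export
has_subsumption <- function(rel, sub, super) {
  stopifnot(inherits(rel, "subsumption_relation"))
  paste0(sub, "\r", super) %in% rel$keys
}

#' Convert a subsumption relation to a tibble
#' @param x A `subsumption_relation`.
#' @param ... Unused.
#' @return Tibble with columns `sub`, `super`.
#' @export
as_tibble.subsumption_relation <- function(x, ...) x$pairs

extract_relation <- function(sat, names) {
  names <- sort(unique(names), method = "radix")
  rows <- purrr::map_dfr(names, function(a) {
    sup <- if (BOT_ATOM %in% sat$S[[a]]) {
      names  # unsatisfiable: subsumed by every name
    } else {
      intersect(sat$S[[a]], names)
    }
    tibble(sub = a, super = sort(unique(sup), method = "radix"))
  })
  subsumption_relation(rows, names)
}

#' Classify a TBox
#'
#' Computes the complete set of entailed name-to-name subsumptions by
#' completion-rule saturation over the normalized axioms: inclusions,
#' equivalences, role inclusions, domain and range restrictions (the range
#' applied at existential introduction), and disjointness (which surfaces
#' as subsumption by the empty class; an unsatisfiable name is reported
#' with a warning and subsumed by every name). Runs in polynomial time in
#' the size of the TBox.
#'
#' @param tbox A [dl_tbox()].
#' @return A `subsumption_relation` over the concept names of the TBox
#'   signature, reflexively and transitively closed.
#' @export
classify <- function(tbox) {
  stopifnot(inherits(tbox, "dl_tbox"))
  st <- normalize_axioms(tbox$axioms)
  sat <- saturate(st, seed_atoms = tbox$concepts)
  unsat <- keep(tbox$concepts, function(a) BOT_ATOM %in% sat$S[[a]])
  if (length(unsat) > 0) {
    warn(sprintf("unsatisfiable concept name(s): %s",
                 paste(unsat, collapse = ", ")))
  }
  extract_relation(sat, tbox$concepts)
}

# ---- expression subsumption ------------------------------------------------

#' Qualifier policy for expression subsumption
#'
#' Qualification normally specializes: an expression refined with a
#' qualifier stays a subtype of its focus concept. Context-setting
#' attributes break this (a finding qualified as known-absent is not an
#' instance of the finding), so expressions carrying one of the listed
#' attributes are not subsumed by their focus concepts. The default list
#' holds a single placeholder (the finding-context attribute); the context
#' hierarchies themselves are out of scope.
#'
#' @param context_attributes Character vector of attribute SCTIDs.
#' @return A `qualifier_policy`.
#' @export
qualifier_policy <- function(context_attributes = "408729009") {
  structure(list(context_attributes = as.character(context_attributes)),
            class = "qualifier_policy")
}

apply_qualifier_policy <- function(expr, policy) {
  if (is.null(policy) || length(policy$context_attributes) == 0) return(expr)
  members <- if (expr$variant == "and") expr$members else list(expr)
  has_context <- any(map_lgl(members, function(m) {
    m$variant %in% c("some", "value") && m$role %in% policy$context_attributes
  }))
  if (!has_context) return(expr)
  kept <- discard(members, function(m) m$variant == "name")
  if (length(kept) == 0) return(expr)
  canonical_form(dl_and(kept))
}

entails_pairs <- function(tbox, a, b) {
  st <- normalize_axioms(tbox$axioms)
  norm_sub(st, atom_expr("__lhs"), prep_expr(a))
  norm_sub(st, prep_expr(a), atom_expr("__lhs"))
  norm_sub(st, atom_expr("__rhs"), prep_expr(b))
  norm_sub(st, prep_expr(b), atom_expr("__rhs"))
  sat <- saturate(st, seed_atoms = c("__lhs", "__rhs"))
  c(ab = "__rhs" %in% sat$S[["__lhs"]] || BOT_ATOM %in% sat$S[["__lhs"]],
    ba = "__lhs" %in% sat$S[["__rhs"]] || BOT_ATOM %in% sat$S[["__rhs"]])
}

#' Decide subsumption between two DL expressions
#'
#' Internalizes both expressions as fresh names equivalent to them and asks
#' the classifier whether the first entails the second under the TBox. Role
#' groups match through the reserved group role: a grouped restriction is
#' subsumed by another exactly when the member conjunctions subsume.
#'
#' @param tbox A [dl_tbox()].
#' @param a,b `dl_expr` objects (concept-name strings accepted).
#' @param policy Optional [qualifier_policy()]; when `a` carries one of the
#'   policy's context attributes, its focus concept names are excluded from
#'   the entailment premises, so subsumption by the focus concept fails.
#' @return `TRUE` or `FALSE`.
#' @export
subsumes <- function(tbox, a, b, policy = NULL) {
  a <- apply_qualifier_policy(canonical_form(as_dl(a)), policy)
  b <- canonical_form(as_dl(b))
  unname(entails_pairs(tbox, a, b)["ab"])
}

#' Decide equivalence between two DL expressions
#'
#' @inheritParams subsumes
#' @return `TRUE` iff each expression subsumes the other under the TBox.
#' @export
equivalent <- function(tbox, a, b) {
  all(entails_pairs(tbox, canonical_form(as_dl(a)), canonical_form(as_dl(b))))
}

# ---- naive oracle ----------------------------------------------------------

#' Naive fixpoint closure (oracle for the classifier)
#'
#' Computes the same relation as [classify()] by exhaustive, unindexed rule
#' application to fixpoint: every completion rule is re-tested against every
#' atom on every pass until nothing changes. Independent code path kept
#' deliberately simple; use it to cross-check [classify()], not for real
#' workloads.
#'
#' @param tbox A [dl_tbox()].
#' @return A `subsumption_relation`.
#' @export
naive_closure <- function(tbox) {
  stopifnot(inherits(tbox, "dl_tbox"))
  st <- normalize_axioms(tbox$axioms, st = new_normalizer(prefix = "__m"))
  atoms <- unique(c(norm_atoms(st), tbox$concepts))
  roles <- norm_roles(st)

  # plain data structures, no indexes, no worklists
  S <- stats::setNames(lapply(atoms, function(a) c(a, TOP_ATOM)), atoms)
  edges <- list()  # each: c(from, role, to)

  super_roles <- function(r) {
    sup <- r
    repeat {
      more <- st$role_sub$super[st$role_sub$sub %in% sup]
      more <- setdiff(more, sup)
      if (length(more) == 0) return(sup)
      sup <- c(sup, more)
    }
  }

  repeat {
    changed <- FALSE
    for (c in atoms) {
      for (i in seq_along(st$gci1$a)) {
        if (st$gci1$a[i] %in% S[[c]] && !(st$gci1$b[i] %in% S[[c]])) {
          S[[c]] <- c(S[[c]], st$gci1$b[i]); changed <- TRUE
        }
      }
      for (i in seq_along(st$gci2$a1)) {
        if (st$gci2$a1[i] %in% S[[c]] && st$gci2$a2[i] %in% S[[c]] &&
            !(st$gci2$b[i] %in% S[[c]])) {
          S[[c]] <- c(S[[c]], st$gci2$b[i]); changed <- TRUE
        }
      }
      for (i in seq_along(st$gci3$a)) {
        if (st$gci3$a[i] %in% S[[c]]) {
          for (s in super_roles(st$gci3$r[i])) {
            key <- list(c(c, s, st$gci3$b[i]))
            if (!any(map_lgl(edges, identical, y = key[[1]]))) {
              edges <- c(edges, key); changed <- TRUE
            }
          }
        }
      }
    }
    for (e in edges) {
      for (i in seq_along(st$ranges$r)) {
        if (st$ranges$r[i] == e[2] && !(st$ranges$b[i] %in% S[[e[3]]])) {
          S[[e[3]]] <- c(S[[e[3]]], st$ranges$b[i]); changed <- TRUE
        }
      }
      for (i in seq_along(st$gci4$r)) {
        if (st$gci4$r[i] == e[2] && st$gci4$a[i] %in% S[[e[3]]] &&
            !(st$gci4$b[i] %in% S[[e[1]]])) {
          S[[e[1]]] <- c(S[[e[1]]], st$gci4$b[i]); changed <- TRUE
        }
      }
      if (BOT_ATOM %in% S[[e[3]]] && !(BOT_ATOM %in% S[[e[1]]])) {
        S[[e[1]]] <- c(S[[e[1]]], BOT_ATOM); changed <- TRUE
      }
      # group composition RG o r <= r
      if (e[2] == RG_ROLE) {
        for (e2 in edges) {
          if (e2[1] == e[3] && e2[2] != RG_ROLE) {
            cand <- c(e[1], e2[2], e2[3])
            if (!any(map_lgl(edges, identical, y = cand))) {
              edges <- c(edges, list(cand)); changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }

  names <- sort(unique(tbox$concepts), method = "radix")
  rows <- purrr::map_dfr(names, function(a) {
    sup <- if (BOT_ATOM %in% S[[a]]) names else intersect(S[[a]], names)
    tibble(sub = a, super = sort(unique(sup), method = "radix"))
  })
  subsumption_relation(rows, names)
}
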
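# Seeded generators shared across test files. Everything is built in code;
# no fixture files.

test_names <- function(n = 25) as.character(seq_len(n))
test_roles <- function(n = 4) as.character(100 + seq_len(n))

# Random TBox in the supported construct subset.
gen_tbox <- function(seed, n_names = 25, n_roles = 4, n_axioms = 30,
                     with_disjoint = FALSE) {
  withr::with_seed(seed, {
    names <- test_names(n_names)
    roles <- test_roles(n_roles)
    nm <- function() dl_name(sample(names, 1))
    kinds <- c("nn", "nsome", "somen", "conj", "rolesub", "domain", "range")
    probs <- c(.35, .2, .15, .12, .06, .06, .06)
    if (with_disjoint) { kinds <- c(kinds, "disjoint"); probs <- c(probs, .05) }
    axioms <- lapply(seq_len(n_axioms), function(i) {
      k <- sample(kinds, 1, prob = probs)
      r <- sample(roles, 1)
      switch(k,
        nn = ax_sub(nm(), nm()),
        nsome = ax_sub(nm(), dl_some(r, nm())),
        somen = ax_sub(dl_some(r, nm()), nm()),
        conj = ax_sub(dl_and(nm(), nm()), nm()),
        rolesub = ax_role_sub(r, sample(roles, 1)),
        domain = ax_domain(r, nm()),
        range = ax_range(r, nm()),
        disjoint = ax_disjoint(nm(), nm()))
    })
    dl_tbox(axioms)
  })
}

# Random DL expression in the CG-expressible shape (groups at top level).
gen_expr <- function(names, roles, depth = 2, top = TRUE) {
  k <- sample(c("name", "and", "some", if (top) "group"), 1)
  if (depth == 0) k <- "name"
  switch(k,
    name = dl_name(sample(names, 1)),
    and = dl_and(lapply(seq_len(sample(2:3, 1)), function(i) {
      gen_expr(names, roles, depth - 1, top = FALSE)
    })),
    some = dl_some(sample(roles, 1),
                   gen_expr(names, roles, depth - 1, top = FALSE)),
    group = dl_group(lapply(seq_len(sample(1:2, 1)), function(i) {
      dl_some(sample(roles, 1), gen_expr(names, roles, depth - 1, top = FALSE))
    })))
}

# Random grouped conjunction (the shape the redundancy rewrites target).
gen_grouped_expr <- function(names, roles) {
  groups <- lapply(seq_len(sample(1:3, 1)), function(i) {
    dl_group(lapply(seq_len(sample(1:3, 1)), function(j) {
      dl_some(sample(roles, 1), dl_name(sample(names, 1)))
    }))
  })
  ungrouped <- lapply(seq_len(sample(0:2, 1)), function(i) {
    dl_some(sample(roles, 1), dl_name(sample(names, 1)))
  })
  plain <- lapply(seq_len(sample(0:2, 1)), function(i) {
    dl_name(sample(names, 1))
  })
  canonical_form(dl_and(c(plain, ungrouped, groups)))
}

# Random compositional-grammar AST (used for serializer round trips).
# Nested expressions always carry the default (equivalent) status: the
# grammar has nowhere to write a status symbol inside a value.
gen_cg_ast <- function(depth = 2, nested = FALSE) {
  ref <- function() {
    sctforge:::cg_concept_ref(as.character(sample(1000:9999, 1)))
  }
  attr <- function(d) {
    value <- if (d > 0 && stats::runif(1) < 0.25) {
      gen_cg_ast(d - 1, nested = TRUE)
    } else if (stats::runif(1) < 0.15) {
      sctforge:::cg_concrete_value("numeric", as.numeric(sample(1:999, 1)))
    } else {
      ref()
    }
    sctforge:::cg_attribute(ref(), value)
  }
  sctforge:::new_cg_expression(
    status = if (nested) "equivalent" else sample(c("equivalent", "subtype"), 1),
    focus = lapply(seq_len(sample(1:3, 1)), function(i) ref()),
    ungrouped = lapply(seq_len(sample(0:2, 1)), function(i) attr(depth)),
    groups = lapply(seq_len(sample(0:2, 1)), function(i) {
      structure(lapply(seq_len(sample(1:2, 1)), function(j) attr(depth - 1)),
                class = "cg_group")
    })
  )
}

# Terms carry no semantics: drop them everywhere for AST comparison.
strip_terms_ast <- function(x) {
  if (is.list(x)) {
    x[names(x) == "term"] <- list(NULL)
    x[] <- lapply(x, strip_terms_ast)
    if (inherits(x, "cg_expression") && inherits(x$defined, "cg_concept_ref")) {
      x$defined["term"] <- list(NULL)
    }
  }
  x
}

# Brute-force reflexive-transitive closure by boolean-matrix squaring.
closure_by_squaring <- function(parent_edges, ids) {
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(m) <- TRUE
  if (nrow(parent_edges) > 0) {
    m[cbind(match(parent_edges$child, ids), match(parent_edges$parent, ids))] <- TRUE
  }
  repeat {
    m2 <- (m %*% m) > 0
    if (identical(m2, m)) return(m)
    m <- m2
  }
}

# Kahn topological sort; returns TRUE iff the edge set is acyclic.
is_acyclic_kahn <- function(edges, ids) {
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  adj <- split(edges$parent, edges$child)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (p in adj[[v]] %||% character()) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  seen == length(ids)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
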
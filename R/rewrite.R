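# Redundancy elimination for grouped expressions. Three rewrites are
# applied to fixpoint, innermost first:
#
#   (3) inside a group, an existential whose filler is more general than a
#       sibling's on the same role is dropped;
#   (2) a group pointwise covered by another group (same roles, fillers at
#       least as specific) is dropped;
#   (1) an ungrouped existential duplicated verbatim inside a group is
#       dropped.
#
# Generality tests between named fillers use the classifier once per TBox;
# complex fillers fall back to full expression subsumption. Each rule only
# removes conjuncts entailed by what remains, so the fixpoint is
# independent of application order and the rewrite preserves equivalence.

#' Rewrite away redundant grouped restrictions
#'
#' @param tbox A [dl_tbox()] supplying the subsumptions used for the
#'   more-general/more-specific tests.
#' @param expr A `dl_expr`; it is canonicalized first.
#' @return The rewritten, canonical `dl_expr`, equivalent to the input
#'   under the TBox.
#' @export
rewrite_redundancies <- function(tbox, expr) {
  stopifnot(inherits(tbox, "dl_tbox"), inherits(expr, "dl_expr"))
  rel <- suppressWarnings(classify(tbox))
  cur <- canonical_form(expr)
  repeat {
    nxt <- canonical_form(rewrite_pass(tbox, rel, cur))
    if (identical(dl_key(nxt), dl_key(cur))) return(nxt)
    cur <- nxt
  }
}

# TRUE iff `general` subsumes `specific` under the TBox (filler test).
filler_ge <- function(tbox, rel, general, specific) {
  if (identical(dl_key(general), dl_key(specific))) return(TRUE)
  if (general$variant == "top") return(TRUE)
  if (general$variant == "name" && specific$variant == "name") {
    return(has_subsumption(rel, specific$sctid, general$sctid))
  }
  subsumes(tbox, specific, general)
}

rewrite_pass <- function(tbox, rel, expr) {
  members <- if (expr$variant == "and") expr$members else list(expr)
  members <- map(members, function(m) rewrite_member(tbox, rel, m))

  groups <- keep(members, function(m) m$variant == "group")
  rest <- discard(members, function(m) m$variant == "group")

  groups <- map(groups, function(g) prune_group(tbox, rel, g))   # rule (3)
  groups <- prune_covered_groups(tbox, rel, groups)              # rule (2)

  # rule (1): ungrouped existential duplicated inside a surviving group
  group_keys <- unlist(map(groups, function(g) map_chr(g$members, dl_key)))
  rest <- discard(rest, function(m) {
    m$variant %in% c("some", "value") && dl_key(m) %in% group_keys
  })

  out <- c(rest, groups)
  if (length(out) == 0) return(dl_top())
  if (length(out) == 1L) out[[1L]] else dl_and(out)
}

# Recurse into fillers so nested conjunctions are rewritten too.
rewrite_member <- function(tbox, rel, m) {
  switch(m$variant,
    some = dl_some(m$role, rewrite_pass(tbox, rel, m$filler)),
    group = dl_group(map(m$members, function(g) rewrite_member(tbox, rel, g))),
    m
  )
}

# Rule (3): within one group drop members with a strictly-more-general (or
# duplicate-up-to-equivalence, keeping the canonically first) filler on the
# same role.
prune_group <- function(tbox, rel, group) {
  ms <- group$members
  if (length(ms) <= 1L) return(group)
  keys <- map_chr(ms, dl_key)
  keep_i <- rep(TRUE, length(ms))
  for (i in seq_along(ms)) {
    if (ms[[i]]$variant != "some") next
    for (j in seq_along(ms)) {
      if (i == j || !keep_i[j] || ms[[j]]$variant != "some") next
      if (!identical(ms[[i]]$role, ms[[j]]$role)) next
      ge_ij <- filler_ge(tbox, rel, ms[[i]]$filler, ms[[j]]$filler)
      if (!ge_ij) next
      ge_ji <- filler_ge(tbox, rel, ms[[j]]$filler, ms[[i]]$filler)
      if (!ge_ji || keys[j] < keys[i]) { keep_i[i] <- FALSE; break }
    }
  }
  dl_group(ms[keep_i])
}

# Rule (2): drop a group whose members are all pointwise covered by another
# group's members (same role, filler at least as specific); between
# mutually covering groups the canonically first survives.
prune_covered_groups <- function(tbox, rel, groups) {
  if (length(groups) <= 1L) return(groups)
  keys <- map_chr(groups, dl_key)
  covers <- function(cover, covered) {
    all(map_lgl(covered$members, function(m) {
      any(map_lgl(cover$members, function(c) {
        m$variant == "some" && c$variant == "some" &&
          identical(c$role, m$role) &&
          filler_ge(tbox, rel, m$filler, c$filler)
      })) || any(map_chr(cover$members, dl_key) == dl_key(m))
    }))
  }
  keep_i <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i == j || !keep_i[j]) next
      if (!covers(groups[[j]], groups[[i]])) next
      if (!covers(groups[[i]], groups[[j]]) || keys[j] < keys[i]) {
        keep_i[i] <- FALSE
        break
      }
    }
  }
  groups[keep_i]
}
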
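# Compositional-grammar expressions: tokenizer, recursive-descent parser,
# and canonical serializer. Two dialects are supported:
#
#   * "paper"    -- the dialect of the worked examples: groups may be written
#                   with plain parentheses in item position as well as
#                   braces, and an attribute may omit the "=" between name
#                   and value (juxtaposition of two concept references in a
#                   refinement context is read as name = value).
#   * "standard" -- braces-only groups, "=" required, "+" accepted as a
#                   synonym for the comma between focus concepts.
#
# Parentheses immediately after "=" always open a nested expression; a
# doubled "((...))" is accepted for the same thing. Terms between pipes
# ("|...|") are labels and never carry semantics.

cg_concept_ref <- function(sctid, term = NULL) {
  assert_sctid(sctid, "concept reference")
  structure(list(sctid = sctid, term = term), class = "cg_concept_ref")
}

cg_concrete_value <- function(kind, value) {
  stopifnot(kind %in% c("numeric", "string"))
  structure(list(kind = kind, value = value), class = "cg_concrete_value")
}

cg_attribute <- function(name, value) {
  stopifnot(inherits(name, "cg_concept_ref"))
  structure(list(name = name, value = value), class = "cg_attribute")
}

new_cg_expression <- function(status = "equivalent", focus = list(),
                              ungrouped = list(), groups = list(),
                              defined = NULL) {
  stopifnot(status %in% c("equivalent", "subtype"))
  structure(list(status = status, defined = defined, focus = focus,
                 ungrouped = ungrouped, groups = groups),
            class = "cg_expression")
}

#' @export
print.cg_expression <- function(x, ...) {
  cat("<cg_expression>", serialize_cg(x, with_terms = TRUE), "\n")
  invisible(x)
}

parse_error <- function(msg, pos) {
  abort(sprintf("parse error at character %d: %s", pos, msg),
        class = "cg_parse_error")
}

# ---- tokenizer -------------------------------------------------------------

cg_tokenize <- function(text, offset = 0L) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value,
                                       pos = pos + offset)
  }
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    start <- i
    if (grepl("^[0-9]$", ch)) {
      j <- i
      while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
      push("SCTID", paste(chars[i:(j - 1L)], collapse = ""), start)
      i <- j
    } else if (ch == "|") {
      j <- i + 1L
      while (j <= n && chars[j] != "|") j <- j + 1L
      if (j > n) parse_error("unterminated term (missing closing '|')", start)
      push("TERM", str_trim(paste(chars[(i + 1L):(j - 1L)], collapse = "")),
           start)
      i <- j + 1L
    } else if (ch == "#") {
      j <- i + 1L
      if (j <= n && chars[j] == "-") j <- j + 1L
      while (j <= n && grepl("^[0-9.]$", chars[j])) j <- j + 1L
      lex <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      val <- suppressWarnings(as.numeric(lex))
      if (j == i + 1L || is.na(val)) parse_error("malformed numeric value", start)
      push("NUMBER", val, start)
      i <- j
    } else if (ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[j] != "\"") j <- j + 1L
      if (j > n) parse_error("unterminated string value", start)
      push("STRING", paste(chars[(i + 1L):(j - 1L)], collapse = ""), start)
      i <- j + 1L
    } else if (ch == "=" && i + 2L <= n && chars[i + 1L] == "=" &&
               chars[i + 2L] == "=") {
      push("STATUS", "equivalent", start); i <- i + 3L
    } else if (ch == "<" && i + 2L <= n && chars[i + 1L] == "<" &&
               chars[i + 2L] == "<") {
      push("STATUS", "subtype", start); i <- i + 3L
    } else if (ch %in% c(":", ",", "=", "{", "}", "(", ")", "+")) {
      type <- c(":" = "COLON", "," = "COMMA", "=" = "EQ", "{" = "LBRACE",
                "}" = "RBRACE", "(" = "LPAREN", ")" = "RPAREN",
                "+" = "PLUS")[[ch]]
      push(type, ch, start)
      i <- i + 1L
    } else if (ch == "." && i == n) {
      i <- i + 1L  # tolerated sentence-final period
    } else {
      parse_error(sprintf("unexpected character '%s'", ch), start)
    }
  }
  toks
}

# Split "lhs === rhs" / "lhs <<< rhs" at the first status operator outside
# pipes and quotes. Returns list(lhs, status, rhs, rhs_offset) or NULL.
split_on_status <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  in_pipe <- FALSE
  in_quote <- FALSE
  n <- length(chars)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "|" && !in_quote) in_pipe <- !in_pipe
    else if (ch == "\"" && !in_pipe) in_quote <- !in_quote
    else if (!in_pipe && !in_quote && i + 2L <= n) {
      three <- paste(chars[i:(i + 2L)], collapse = "")
      if (three %in% c("===", "<<<")) {
        return(list(
          lhs = substr(text, 1L, i - 1L),
          status = if (three == "===") "equivalent" else "subtype",
          rhs = substr(text, i + 3L, nchar(text)),
          rhs_offset = i + 2L
        ))
      }
    }
  }
  NULL
}

# ---- parser ----------------------------------------------------------------

#' Parse a compositional-grammar expression
#'
#' Parses an expression string into an abstract syntax tree capturing the
#' definition status (`===` equivalent, the default, or `<<<` subtype), the
#' optionally named defined concept on the left of the status operator, the
#' focus concepts, ungrouped attribute refinements, attribute groups, nested
#' expressions, and concrete (numeric `#...` or quoted string) values.
#' Whitespace and terms (`|...|` labels) never affect the parsed semantics.
#'
#' @param text Expression string.
#' @param dialect `"paper"` or `"standard"`; see the package vignette for
#'   the differences (parenthesized groups and juxtaposed name/value pairs
#'   are paper-dialect only).
#' @return A `cg_expression`.
#' @export
parse_cg <- function(text, dialect = c("paper", "standard")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(str_trim(text))) parse_error("empty expression", 1L)

  defined <- NULL
  status <- "equivalent"
  body_text <- text
  body_offset <- 0L
  sp <- split_on_status(text)
  if (!is.null(sp)) {
    status <- sp$status
    body_text <- sp$rhs
    body_offset <- sp$rhs_offset
    lhs <- str_trim(sp$lhs)
    if (nzchar(lhs)) defined <- parse_defined(lhs, dialect)
  }

  toks <- cg_tokenize(body_text, offset = body_offset)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  expr <- parse_body(st, status, dialect)
  if (st$i <= length(st$toks)) {
    parse_error("trailing input after expression", peek(st)$pos)
  }
  expr["defined"] <- list(defined)
  expr
}

# The defined concept left of the status operator: a concept reference
# ("73211009 |Diabetes mellitus|") or a bare textual label.
parse_defined <- function(lhs, dialect) {
  if (grepl("^[0-9]+(\\s*\\|[^|]*\\|)?$", lhs)) {
    toks <- cg_tokenize(lhs)
    term <- if (length(toks) > 1L) toks[[2L]]$value else NULL
    cg_concept_ref(toks[[1L]]$value, term)
  } else {
    structure(list(label = lhs), class = "cg_label")
  }
}

peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
advance <- function(st) { t <- peek(st); st$i <- st$i + 1L; t }
expect <- function(st, type, what) {
  t <- peek(st)
  if (is.null(t)) parse_error(sprintf("unexpected end of input, expected %s", what),
                              end_pos(st))
  if (t$type != type) parse_error(sprintf("expected %s", what), t$pos)
  advance(st)
}
end_pos <- function(st) {
  if (length(st$toks) > 0) st$toks[[length(st$toks)]]$pos + 1L else 1L
}

# body := item (("," | "+") item)* [":" refinement-item (("," ) item)*]
# Items before any colon may be focus concepts, attributes, or groups (the
# worked examples freely mix them); after a colon only attributes and groups
# are allowed.
parse_body <- function(st, status, dialect) {
  focus <- list()
  ungrouped <- list()
  groups <- list()
  in_refinement <- FALSE
  repeat {
    t <- peek(st)
    if (is.null(t)) break
    if (t$type == "COLON") {
      advance(st)
      in_refinement <- TRUE
      next
    }
    item <- parse_item(st, dialect, in_refinement)
    if (inherits(item, "cg_concept_ref")) {
      focus[[length(focus) + 1L]] <- item
    } else if (inherits(item, "cg_attribute")) {
      ungrouped[[length(ungrouped) + 1L]] <- item
    } else { # group
      groups[[length(groups) + 1L]] <- item
    }
    t <- peek(st)
    if (!is.null(t) && t$type %in% c("COMMA", "PLUS")) {
      if (t$type == "PLUS" && dialect != "standard") {
        parse_error("'+' between focus concepts requires dialect = \"standard\"",
                    t$pos)
      }
      advance(st)
      next
    }
    if (!is.null(t) && t$type == "COLON") next
    break
  }
  if (length(focus) == 0) {
    parse_error("expression has no focus concept", end_pos(st))
  }
  new_cg_expression(status, focus, ungrouped, groups)
}

parse_item <- function(st, dialect, in_refinement) {
  t <- peek(st)
  if (is.null(t)) parse_error("unexpected end of input", end_pos(st))
  if (t$type == "LBRACE" ||
      (t$type == "LPAREN" && dialect == "paper")) {
    return(parse_group(st, dialect))
  }
  if (t$type == "LPAREN") {
    parse_error("parenthesized groups require dialect = \"paper\" (use braces)",
                t$pos)
  }
  if (t$type != "SCTID") {
    parse_error("expected a concept identifier, group, or refinement", t$pos)
  }
  ref <- parse_concept_ref(st)
  nxt <- peek(st)
  if (!is.null(nxt) && nxt$type == "EQ") {
    advance(st)
    return(cg_attribute(ref, parse_value(st, dialect)))
  }
  if (!is.null(nxt) && nxt$type == "SCTID" && dialect == "paper") {
    # juxtaposition: "name value" without "="
    return(cg_attribute(ref, parse_concept_ref(st)))
  }
  if (in_refinement) {
    parse_error("expected '=' (or a juxtaposed value in dialect = \"paper\") after attribute name",
                if (is.null(nxt)) end_pos(st) else nxt$pos)
  }
  ref
}

parse_concept_ref <- function(st) {
  t <- expect(st, "SCTID", "a concept identifier")
  term <- NULL
  nxt <- peek(st)
  if (!is.null(nxt) && nxt$type == "TERM") {
    term <- advance(st)$value
  }
  cg_concept_ref(t$value, term)
}

# group := ("{" | "(") attribute ("," attribute)* ("}" | ")")
parse_group <- function(st, dialect) {
  open <- advance(st)
  close <- if (open$type == "LBRACE") "RBRACE" else "RPAREN"
  members <- list()
  repeat {
    item <- parse_item(st, dialect, in_refinement = TRUE)
    if (!inherits(item, "cg_attribute")) {
      parse_error("attribute groups may only contain attribute refinements",
                  open$pos)
    }
    members[[length(members) + 1L]] <- item
    t <- peek(st)
    if (!is.null(t) && t$type == "COMMA") { advance(st); next }
    break
  }
  expect(st, close, if (close == "RBRACE") "'}'" else "')'")
  structure(members, class = "cg_group")
}

parse_value <- function(st, dialect) {
  t <- peek(st)
  if (is.null(t)) parse_error("missing attribute value", end_pos(st))
  if (t$type == "NUMBER") {
    advance(st)
    return(cg_concrete_value("numeric", t$value))
  }
  if (t$type == "STRING") {
    advance(st)
    return(cg_concrete_value("string", t$value))
  }
  if (t$type == "SCTID") {
    return(parse_concept_ref(st))
  }
  if (t$type == "LPAREN") {
    advance(st)
    doubled <- FALSE
    nxt <- peek(st)
    # "((" opens the same nested expression as "("
    if (!is.null(nxt) && nxt$type == "LPAREN") {
      save <- st$i
      advance(st)
      inner <- tryCatch(parse_nested(st, dialect, doubled = TRUE),
                        cg_parse_error = function(e) NULL)
      if (!is.null(inner)) return(inner)
      st$i <- save
    }
    return(parse_nested(st, dialect, doubled = FALSE))
  }
  parse_error("expected a concept, nested expression, or concrete value",
              t$pos)
}

parse_nested <- function(st, dialect, doubled) {
  expr <- parse_nested_body(st, dialect)
  expect(st, "RPAREN", "')'")
  if (doubled) expect(st, "RPAREN", "')'")
  expr
}

# A nested expression body runs until the unbalanced closing parenthesis.
parse_nested_body <- function(st, dialect) {
  focus <- list()
  ungrouped <- list()
  groups <- list()
  repeat {
    item <- parse_item(st, dialect, in_refinement = FALSE)
    if (inherits(item, "cg_concept_ref")) {
      focus[[length(focus) + 1L]] <- item
    } else if (inherits(item, "cg_attribute")) {
      ungrouped[[length(ungrouped) + 1L]] <- item
    } else {
      groups[[length(groups) + 1L]] <- item
    }
    t <- peek(st)
    if (!is.null(t) && t$type %in% c("COMMA", "COLON")) { advance(st); next }
    break
  }
  if (length(focus) == 0) {
    parse_error("nested expression has no focus concept", end_pos(st))
  }
  new_cg_expression("equivalent", focus, ungrouped, groups)
}

# ---- serializer ------------------------------------------------------------

#' Serialize a compositional-grammar expression
#'
#' Writes an expression back to text. Element order in the AST is preserved,
#' so `parse_cg(serialize_cg(x, with_terms = TRUE))` reproduces `x`; pass
#' the result of [cg_canonical()] to obtain the sorted, term-free normal
#' form used for equivalence testing.
#'
#' @param expr A `cg_expression`.
#' @param with_terms Include `|term|` labels where the AST carries them?
#' @return A single string.
#' @export
serialize_cg <- function(expr, with_terms = FALSE) {
  stopifnot(inherits(expr, "cg_expression"))
  out <- serialize_body(expr, with_terms)
  prefix <- ""
  if (!is.null(expr$defined)) {
    lhs <- if (inherits(expr$defined, "cg_label")) {
      expr$defined$label
    } else {
      serialize_ref(expr$defined, with_terms)
    }
    prefix <- paste0(lhs, if (expr$status == "subtype") " <<< " else " === ")
  } else if (expr$status == "subtype") {
    prefix <- "<<< "
  }
  paste0(prefix, out)
}

serialize_body <- function(expr, with_terms) {
  focus <- map_chr(expr$focus, serialize_ref, with_terms = with_terms)
  refs <- c(
    map_chr(expr$ungrouped, serialize_attr, with_terms = with_terms),
    map_chr(expr$groups, serialize_group, with_terms = with_terms)
  )
  paste0(paste(focus, collapse = ", "),
         if (length(refs) > 0) paste0(": ", paste(refs, collapse = ", ")))
}

serialize_ref <- function(ref, with_terms) {
  paste0(ref$sctid,
         if (with_terms && !is.null(ref$term)) paste0(" |", ref$term, "|"))
}

serialize_attr <- function(attr, with_terms) {
  value <- attr$value
  rhs <- if (inherits(value, "cg_concept_ref")) {
    serialize_ref(value, with_terms)
  } else if (inherits(value, "cg_concrete_value")) {
    if (value$kind == "numeric") {
      paste0("#", format(value$value, scientific = FALSE, trim = TRUE))
    } else {
      paste0("\"", value$value, "\"")
    }
  } else { # nested expression
    paste0("(", serialize_body(value, with_terms), ")")
  }
  paste0(serialize_ref(attr$name, with_terms), " = ", rhs)
}

serialize_group <- function(group, with_terms) {
  paste0("{", paste(map_chr(group, serialize_attr, with_terms = with_terms),
                    collapse = ", "), "}")
}

# ---- canonical form --------------------------------------------------------

#' Canonicalize a compositional-grammar expression
#'
#' Produces the normal form used to measure expression equivalence: the
#' defined-concept label and all terms are dropped, and focus concepts,
#' ungrouped attributes, group members, and groups are each sorted by their
#' lexicographic term-free serialization (identifiers are compared as
#' strings, which is what makes "129249002" sort before "7246002").
#'
#' @param expr A `cg_expression`.
#' @return A canonical `cg_expression`; serialize it with
#'   `serialize_cg(x, with_terms = FALSE)` for the printed normal form.
#' @export
cg_canonical <- function(expr) {
  stopifnot(inherits(expr, "cg_expression"))
  canon_ref <- function(r) cg_concept_ref(r$sctid)
  canon_attr <- function(a) {
    v <- a$value
    v2 <- if (inherits(v, "cg_concept_ref")) canon_ref(v)
          else if (inherits(v, "cg_expression")) cg_canonical(v)
          else v
    cg_attribute(canon_ref(a$name), v2)
  }
  focus <- map(expr$focus, canon_ref)
  focus <- focus[order(map_chr(focus, "sctid"), method = "radix")]
  focus <- focus[!duplicated(map_chr(focus, "sctid"))]
  ungrouped <- map(expr$ungrouped, canon_attr)
  ukeys <- map_chr(ungrouped, serialize_attr, with_terms = FALSE)
  ungrouped <- ungrouped[order(ukeys, method = "radix")][!duplicated(sort(ukeys, method = "radix"))]
  groups <- map(expr$groups, function(g) {
    members <- map(g, canon_attr)
    keys <- map_chr(members, serialize_attr, with_terms = FALSE)
    structure(members[order(keys, method = "radix")][!duplicated(sort(keys, method = "radix"))],
              class = "cg_group")
  })
  gkeys <- map_chr(groups, serialize_group, with_terms = FALSE)
  groups <- groups[order(gkeys, method = "radix")][!duplicated(sort(gkeys, method = "radix"))]
  new_cg_expression(expr$status, focus, ungrouped, groups)
}

#' Term-free normal form of an expression string
#'
#' @param text Expression string.
#' @param dialect Passed to [parse_cg()].
#' @return The canonical, term-free serialization.
#' @export
cg_normal_form <- function(text, dialect = c("paper", "standard")) {
  serialize_cg(cg_canonical(parse_cg(text, dialect)), with_terms = FALSE)
}

#' Worked example expressions
#'
#' The eight post-/pre-coordination example expressions (plus the unnumbered
#' radius-fracture refinement) in the paper dialect, usable as parser input
#' and as seeds for the ontology-building examples.
#'
#' @return Named character vector (`ex1` ... `ex8`, `radius_fracture`).
#' @export
cg_examples <- function() {
  c(
    ex1 = paste0(
      "73211009 |Diabetes mellitus| <<< 126877002|disorder of glucose metabolism|, ",
      "362969004|disorder of endocrine system|, ",
      "363698007|finding site| 113331007|structure of endocrine system|."),
    ex2 = "Needle biopsy of kidney === 7246002|Kidney biopsy|, 129249002 |Needle biopsy|.",
    ex3 = paste0(
      "===71388002 |procedure|: 405815000|procedure device| = 122456005 |laser device|, ",
      "260686004 |method| = 129304002 |excision - action|, ",
      "405813007 |procedure site - direct| = 15497006 |ovarian structure|"),
    ex5 = paste0(
      "111613008|closed skull fracture with intracranial injury|===",
      "451000119106|closed injury of head|, 371162008|closed fracture of skull|, ",
      "(116676008|associated morphology|= 450695007|closed traumatic abnormality|, ",
      "363698007|finding site|= 128319008|intracranial structure|), ",
      "(116676008|associated morphology|= 20946005|fracture, closed|, ",
      "363698007|finding site|= 89546000|bone structure of cranium|)"),
    ex6 = paste0(
      "27658006 |amoxicillin|: 411116001 |has dose form| = 385049006 |capsule|, ",
      "{127489000 |has active ingredient| = 372687004 |amoxicillin|, ",
      "111115|has basis of strength| = (111115 |amoxicillin only|: ",
      "111115|strength magnitude| = #500, ",
      "111115|strength unit| = 258684004 |mg|)}"),
    ex7 = paste0(
      "periodic fever accompanied by chills === 274640006|fever with chills|: ",
      "246456000|episodicity| = 81591007|periodic|"),
    ex8 = paste0(
      "87628006|bacterial infectious disease|: ",
      "246075003|causative agent|= 9861002|streptococcus pneumonia|, ",
      "363698007|finding site|= (45653009|structure of upper lobe of lung|,",
      "272741003|laterality|= 7771000|left|)"),
    radius_fracture = "===125605004|Fracture of bone|: 363698007|Finding site| = 181940002|Radius|"
  )
}
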
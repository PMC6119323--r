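ex <- cg_examples()

test_that("the combination example parses to its printed normal form", {
  ast <- parse_cg(ex[["ex2"]])
  expect_identical(ast$status, "equivalent")
  expect_setequal(purrr::map_chr(ast$focus, "sctid"),
                  c("7246002", "129249002"))
  expect_length(ast$ungrouped, 0)
  expect_identical(cg_normal_form(ex[["ex2"]]), "129249002, 7246002")
  expect_identical(cg_normal_form("129249002, 7246002"),
                   "129249002, 7246002")
})

test_that("juxtaposed name/value pairs parse in the paper dialect only", {
  ast <- parse_cg(ex[["ex1"]], dialect = "paper")
  expect_identical(ast$status, "subtype")
  expect_identical(ast$defined$sctid, "73211009")
  expect_setequal(purrr::map_chr(ast$focus, "sctid"),
                  c("126877002", "362969004"))
  expect_length(ast$ungrouped, 1)
  expect_identical(ast$ungrouped[[1]]$name$sctid, "363698007")
  expect_identical(ast$ungrouped[[1]]$value$sctid, "113331007")
  expect_error(parse_cg(ex[["ex1"]], dialect = "standard"), "parse error")
})

test_that("parenthesized groups after the focus list parse as groups", {
  ast <- parse_cg(ex[["ex5"]])
  expect_identical(ast$defined$sctid, "111613008")
  expect_setequal(purrr::map_chr(ast$focus, "sctid"),
                  c("451000119106", "371162008"))
  expect_length(ast$groups, 2)
  g1 <- purrr::map_chr(ast$groups[[1]], function(a) a$name$sctid)
  expect_setequal(g1, c("116676008", "363698007"))
})

test_that("concrete values and nesting parse as printed in the drug example", {
  ast <- parse_cg(ex[["ex6"]])
  expect_identical(purrr::map_chr(ast$focus, "sctid"), "27658006")
  expect_length(ast$ungrouped, 1)
  expect_identical(ast$ungrouped[[1]]$value$sctid, "385049006")
  expect_length(ast$groups, 1)
  grp <- ast$groups[[1]]
  expect_length(grp, 2)
  nested <- grp[[2]]$value
  expect_s3_class(nested, "cg_expression")
  kinds <- purrr::map_chr(nested$ungrouped, function(a) class(a$value)[1])
  num <- nested$ungrouped[[which(kinds == "cg_concrete_value")]]
  expect_identical(num$value$kind, "numeric")
  expect_identical(num$value$value, 500)
  unit <- nested$ungrouped[[which(kinds == "cg_concept_ref")]]
  expect_identical(unit$value$sctid, "258684004")
})

test_that("malformed expressions fail with a character offset", {
  expect_error(parse_cg("==="), "no focus concept")
  expect_error(parse_cg("   "), "empty expression")
  expect_error(parse_cg("123: 456 ="), "parse error")
  expect_error(parse_cg("123 |unterminated"), "missing closing")
  expect_error(parse_cg("{123 = 456"), "expected '\\}'")
  expect_error(parse_cg("abc"), "unexpected character")
  err <- tryCatch(parse_cg("123, abc"), error = function(e) conditionMessage(e))
  expect_match(err, "character 6")
})

test_that("parse-serialize-parse is the identity on all worked examples", {
  for (n in names(ex)) {
    ast <- parse_cg(ex[[n]])
    expect_identical(parse_cg(serialize_cg(ast, with_terms = TRUE)), ast,
                     label = n)
    expect_identical(parse_cg(serialize_cg(ast, with_terms = FALSE)),
                     strip_terms_ast(ast), label = n)
  }
})

test_that("serializer round trip holds on 500 random ASTs", {
  withr::with_seed(42, {
    for (i in 1:500) {
      ast <- gen_cg_ast()
      text <- serialize_cg(ast, with_terms = FALSE)
      expect_identical(parse_cg(text), ast, label = paste("ast", i))
      canon <- cg_canonical(ast)
      expect_identical(cg_canonical(parse_cg(serialize_cg(canon))), canon)
    }
  })
})

test_that("terms never change the parsed semantics", {
  for (n in names(ex)) {
    with_terms <- parse_cg(ex[[n]])
    stripped <- parse_cg(serialize_cg(with_terms, with_terms = FALSE))
    expect_identical(serialize_cg(cg_canonical(with_terms)),
                     serialize_cg(cg_canonical(stripped)), label = n)
  }
})

test_that("the two dialects agree on braces-only expressions", {
  texts <- c("129249002, 7246002",
             "27658006: 411116001 = 385049006, {127489000 = 372687004}",
             "<<< 125605004: 363698007 = 181940002")
  for (t in texts) {
    expect_identical(parse_cg(t, "paper"), parse_cg(t, "standard"), label = t)
  }
  # '+' joins focus concepts in the standard dialect only
  expect_identical(purrr::map_chr(parse_cg("7246002 + 129249002",
                                           "standard")$focus, "sctid"),
                   c("7246002", "129249002"))
  expect_error(parse_cg("7246002 + 129249002", "paper"), "standard")
})

test_that("canonical ordering is lexicographic on the identifier strings", {
  ast <- parse_cg("9861002, 129249002, 7246002")
  expect_identical(serialize_cg(cg_canonical(ast)),
                   "129249002, 7246002, 9861002")
})
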
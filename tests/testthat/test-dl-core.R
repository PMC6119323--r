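ex <- cg_examples()

test_that("canonical form flattens, deduplicates, sorts, and is idempotent", {
  a <- dl_name("129249002"); b <- dl_name("7246002")
  e <- dl_and(b, a)
  expect_identical(purrr::map_chr(canonical_form(e)$members, "sctid"),
                   c("129249002", "7246002"))
  # duplicate collapse unwraps a one-member conjunction
  expect_identical(canonical_form(dl_and(a, a)), a)
  # nested conjunctions flatten
  nested <- dl_and(a, dl_and(b, dl_name("9861002")))
  expect_length(canonical_form(nested)$members, 3)
  # idempotence on shuffled members, 100 random expressions
  withr::with_seed(7, {
    for (i in 1:100) {
      e <- gen_expr(test_names(), test_roles(), depth = 3)
      c1 <- canonical_form(e)
      expect_identical(canonical_form(c1), c1)
      if (e$variant == "and") {
        shuffled <- dl_and(sample(e$members))
        expect_identical(dl_format(canonical_form(shuffled)), dl_format(c1))
      }
    }
  })
})

test_that("the skull-fracture example translates to its printed DL form", {
  out <- cg_to_dl(parse_cg(ex[["ex5"]]))
  expect_identical(out$kind, "equivalent")
  e <- out$expr
  expect_identical(e$variant, "and")
  names <- purrr::map_chr(purrr::keep(e$members, ~ .x$variant == "name"),
                          "sctid")
  expect_setequal(names, c("451000119106", "371162008"))
  groups <- purrr::keep(e$members, ~ .x$variant == "group")
  expect_length(groups, 2)
  rendered <- purrr::map_chr(groups, dl_format)
  expect_true(any(grepl("∃116676008.450695007 ⊓ ∃363698007.128319008",
                        rendered, fixed = TRUE)))
  expect_true(any(grepl("∃116676008.20946005 ⊓ ∃363698007.89546000",
                        rendered, fixed = TRUE)))
})

test_that("the drug example translates with its concrete strength value", {
  out <- cg_to_dl(parse_cg(ex[["ex6"]]))
  e <- out$expr
  group <- purrr::keep(e$members, ~ .x$variant == "group")[[1]]
  basis <- purrr::keep(group$members, ~ .x$variant == "some" &&
                         .x$filler$variant == "and")[[1]]
  filler_kinds <- purrr::map_chr(basis$filler$members, "variant")
  expect_true("value" %in% filler_kinds)
  value <- purrr::keep(basis$filler$members, ~ .x$variant == "value")[[1]]
  expect_identical(value$value, 500)
  expect_identical(value$kind, "numeric")
})

test_that("a bare concept translates to a name with equivalent status", {
  out <- cg_to_dl(parse_cg("73211009"))
  expect_identical(out$expr, dl_name("73211009"))
  expect_identical(out$kind, "equivalent")
})

test_that("dl_to_cg inverts cg_to_dl", {
  # printed example: the combination normal form
  cg <- dl_to_cg(dl_and(dl_name("129249002"), dl_name("7246002")))
  expect_identical(serialize_cg(cg), "129249002, 7246002")
  expect_identical(serialize_cg(dl_to_cg(dl_name("73211009"))), "73211009")
  # round trip on 200 random CG-shaped expressions (translations of random
  # grammar ASTs, so every existential filler carries a focus concept)
  withr::with_seed(11, {
    for (i in 1:200) {
      e <- canonical_form(cg_to_dl(gen_cg_ast())$expr)
      back <- cg_to_dl(dl_to_cg(e))$expr
      expect_identical(dl_format(back), dl_format(e), label = paste("expr", i))
    }
  })
  # a group inside a filler has no CG rendering
  bad <- dl_some("101", dl_group(dl_some("102", dl_name("1"))))
  expect_error(dl_to_cg(bad), "no compositional-grammar rendering")
})

test_that("unsupported constructors do not exist at the type level", {
  expect_error(dl_name("not-digits"))
  expect_error(dl_group(dl_name("1")), "existential")
  expect_error(dl_and())
})

test_that("extensions follow the standard set semantics", {
  interp <- dl_interpretation(
    domain = c("a", "b", "c"),
    classes = list(`1` = c("a", "b"), `2` = c("b", "c")),
    roles = list(`101` = rbind(c("a", "b"), c("b", "c")))
  )
  expect_setequal(extension(interp, dl_top()), c("a", "b", "c"))
  expect_identical(extension(interp, dl_bottom()), character(0))
  expect_setequal(extension(interp, dl_and(dl_name("1"), dl_name("2"))), "b")
  expect_setequal(extension(interp, dl_some("101", dl_name("2"))),
                  c("a", "b"))
  # an empty role extension empties every existential over it
  empty <- dl_interpretation(c("a"), list(`1` = "a"), list())
  expect_identical(extension(empty, dl_some("101", dl_name("1"))),
                   character(0))
})

random_interp <- function(names, roles, n = 4) {
  domain <- paste0("d", seq_len(n))
  dl_interpretation(
    domain = domain,
    classes = stats::setNames(
      lapply(names, function(x) sample(domain, sample(0:n, 1))), names),
    roles = stats::setNames(lapply(roles, function(r) {
      k <- sample(0:(n * 2), 1)
      if (k == 0) matrix(character(), ncol = 2)
      else cbind(sample(domain, k, TRUE), sample(domain, k, TRUE))
    }), roles)
  )
}

test_that("set-algebra identities hold on 500 random interpretation/expression pairs", {
  names <- test_names(6)
  roles <- test_roles(3)
  withr::with_seed(23, {
    for (i in 1:500) {
      interp <- random_interp(names, roles)
      a <- gen_expr(names, roles, depth = 2)
      b <- gen_expr(names, roles, depth = 2)
      expect_setequal(extension(interp, dl_and(a, b)),
                      intersect(extension(interp, a), extension(interp, b)))
      r <- sample(roles, 1)
      pairs <- interp$roles[[r]]
      manual <- unique(pairs[pairs[, 2] %in% extension(interp, a), 1])
      expect_setequal(extension(interp, dl_some(r, a)), manual)
      expect_true(all(extension(interp, a) %in% extension(interp, dl_top())))
    }
  })
})

test_that("is_model agrees with an independent per-axiom evaluator", {
  expect_true(is_model(dl_interpretation("a"), dl_tbox(list())))
  bad <- dl_interpretation(c("a"), list(`1` = "a", `2` = character()))
  expect_false(is_model(bad, dl_tbox(list(ax_sub("1", "2")))))

  check_axiom <- function(interp, ax) {
    # independent set-theoretic re-evaluation
    ext <- function(e) extension(interp, e)
    switch(ax$kind,
      sub = all(ext(ax$lhs) %in% ext(ax$rhs)),
      equiv = setequal(ext(ax$lhs), ext(ax$rhs)),
      disjoint = length(intersect(ext(ax$a), ext(ax$b))) == 0,
      role_sub = {
        sub <- interp$roles[[ax$sub]]; sup <- interp$roles[[ax$super]]
        sub_keys <- if (is.null(sub)) character() else paste(sub[, 1], sub[, 2])
        sup_keys <- if (is.null(sup)) character() else paste(sup[, 1], sup[, 2])
        all(sub_keys %in% sup_keys)
      },
      domain = {
        p <- interp$roles[[ax$role]]
        is.null(p) || all(p[, 1] %in% ext(ax$class))
      },
      range = {
        p <- interp$roles[[ax$role]]
        is.null(p) || all(p[, 2] %in% ext(ax$class))
      })
  }
  tb <- snapshot_tbox(paper_fixture())
  withr::with_seed(31, {
    for (i in 1:20) {
      interp <- random_interp(tb$concepts, union(tb$roles, "RG"), n = 5)
      expect_identical(is_model(interp, tb),
                       all(purrr::map_lgl(tb$axioms, check_axiom,
                                          interp = interp)))
    }
  })
  withr::with_seed(32, {
    for (s in 1:30) {
      tbr <- gen_tbox(s, n_names = 8, n_roles = 3, n_axioms = 12)
      interp <- random_interp(tbr$concepts, tbr$roles, n = 4)
      expect_identical(is_model(interp, tbr),
                       all(purrr::map_lgl(tbr$axioms, check_axiom,
                                          interp = interp)))
    }
  })
})
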
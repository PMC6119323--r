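fixture_tb <- snapshot_tbox(paper_fixture())

test_that("classification of the fixture recovers the printed supertypes", {
  rel <- classify(fixture_tb)
  expect_true(has_subsumption(rel, "73211009", "126877002"))
  expect_true(has_subsumption(rel, "73211009", "362969004"))
  expect_true(has_subsumption(rel, "73211009", "404684003"))
  expect_false(has_subsumption(rel, "126877002", "73211009"))
  # every name subsumes itself
  expect_true(all(purrr::map_lgl(rel$names, function(n)
    has_subsumption(rel, n, n))))
})

test_that("chained and role-mediated entailments are derived", {
  tb <- dl_tbox(list(
    ax_sub("1", "2"), ax_sub("2", "3"),
    ax_sub("4", dl_some("101", dl_name("1"))),
    ax_sub(dl_some("101", dl_name("3")), dl_name("5")),
    ax_role_sub("101", "102"),
    ax_sub(dl_some("102", dl_name("3")), dl_name("6")),
    ax_domain("103", "7"),
    ax_sub("8", dl_some("103", dl_top())),
    ax_range("104", "9"),
    ax_sub("10", dl_some("104", dl_name("2"))),
    ax_sub(dl_some("104", dl_name("9")), dl_name("11"))
  ))
  rel <- classify(tb)
  expect_true(has_subsumption(rel, "1", "3"))      # transitivity
  expect_true(has_subsumption(rel, "4", "5"))      # existential + filler walk
  expect_true(has_subsumption(rel, "4", "6"))      # through the role hierarchy
  expect_true(has_subsumption(rel, "8", "7"))      # domain restriction
  expect_true(has_subsumption(rel, "10", "11"))    # range feeds the filler
  expect_false(has_subsumption(rel, "5", "4"))
})

test_that("disjointness surfaces as an unsatisfiability warning", {
  tb <- dl_tbox(list(ax_sub("1", "2"), ax_sub("1", "3"),
                     ax_disjoint("2", "3")))
  expect_warning(rel <- classify(tb), "unsatisfiable.*1")
  expect_true(has_subsumption(rel, "1", "2"))
  expect_true(has_subsumption(rel, "1", "3"))
})

test_that("classify matches the naive fixpoint oracle on the fixture and random TBoxes", {
  expect_identical(classify(fixture_tb)$pairs, naive_closure(fixture_tb)$pairs)
  for (seed in 1:25) {
    tb <- gen_tbox(seed, n_names = 15, n_roles = 3, n_axioms = 20,
                   with_disjoint = TRUE)
    expect_identical(suppressWarnings(classify(tb))$pairs,
                     suppressWarnings(naive_closure(tb))$pairs,
                     label = paste("seed", seed))
  }
})

test_that("adding axioms never removes entailed subsumptions", {
  withr::with_seed(5, {
    for (i in 1:10) {
      tb <- gen_tbox(i, n_names = 12, n_roles = 3, n_axioms = 15)
      extra <- ax_sub(dl_name(sample(test_names(12), 1)),
                      dl_name(sample(test_names(12), 1)))
      tb2 <- dl_tbox(c(tb$axioms, list(extra)))
      before <- suppressWarnings(classify(tb))$keys
      after <- suppressWarnings(classify(tb2))$keys
      expect_true(all(before %in% after))
    }
  })
})

test_that("expression subsumption handles the qualification example", {
  ex <- cg_examples()
  a <- cg_to_dl(parse_cg(ex[["ex7"]]))$expr
  expect_true(subsumes(fixture_tb, a, "274640006"))
  expect_true(subsumes(fixture_tb, a, "404684003"))
  expect_true(subsumes(fixture_tb, a, a))
  expect_false(subsumes(fixture_tb, dl_name("274640006"), a))
})

test_that("a context attribute suppresses subsumption by the focus concept", {
  policy <- qualifier_policy("408729009")
  qualified <- dl_and(dl_name("274640006"),
                      dl_some("408729009", dl_name("81591007")))
  plain <- dl_and(dl_name("274640006"),
                  dl_some("246456000", dl_name("81591007")))
  expect_false(subsumes(fixture_tb, qualified, "274640006", policy = policy))
  expect_true(subsumes(fixture_tb, plain, "274640006", policy = policy))
  expect_true(subsumes(fixture_tb, qualified, "274640006"))  # no policy
})

test_that("equivalence is two-way subsumption", {
  ex <- cg_examples()
  e2 <- cg_to_dl(parse_cg(ex[["ex2"]]))$expr
  expect_true(equivalent(dl_tbox(list()), e2,
                         dl_and(dl_name("129249002"), dl_name("7246002"))))
  expect_true(equivalent(fixture_tb, e2, canonical_form(e2)))
  expect_false(equivalent(fixture_tb, dl_name("73211009"),
                          dl_name("126877002")))
})

test_that("a grouped restriction entails its ungrouped member", {
  # the group role composes with member roles, so an attribute stated
  # inside a group still holds of the source concept
  g <- dl_group(dl_some("101", dl_name("1")), dl_some("102", dl_name("2")))
  expect_true(subsumes(dl_tbox(list()), g, dl_some("101", dl_name("1"))))
  expect_false(subsumes(dl_tbox(list()), dl_some("101", dl_name("1")), g))
})

test_that("subsumes agrees with bounded counter-model search", {
  names <- test_names(10)
  roles <- test_roles(3)
  withr::with_seed(17, {
    tb <- gen_tbox(3, n_names = 10, n_roles = 3, n_axioms = 15)
    for (i in 1:60) {
      a <- gen_expr(names, roles, depth = 2)
      b <- gen_expr(names, roles, depth = 2)
      s <- suppressWarnings(subsumes(tb, a, b))
      cm <- find_countermodel(tb, a, b, max_domain = 6)
      expect_identical(s, is.null(cm), label = paste("pair", i))
      if (!is.null(cm)) {
        expect_true(is_model(cm, tb))
        expect_gt(length(setdiff(extension(cm, sctforge:::prep_expr(a)),
                                 extension(cm, sctforge:::prep_expr(b)))), 0)
      }
    }
  })
})

test_that("derived subsumptions are sound in repaired random models", {
  rel <- classify(fixture_tb)
  pairs <- tidy(rel)
  for (s in 1:5) {
    m <- random_model(fixture_tb, domain_size = 5, seed = s)
    expect_true(is_model(m, fixture_tb))
    ok <- purrr::map_lgl(seq_len(nrow(pairs)), function(i) {
      all(extension(m, dl_name(pairs$sub[i])) %in%
            extension(m, dl_name(pairs$super[i])))
    })
    expect_true(all(ok), label = paste("model", s))
  }
})
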
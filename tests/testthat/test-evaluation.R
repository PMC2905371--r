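test_that("overlap score follows the squared-intersection form", {
  expect_equal(overlap_score(letters[1:5], letters[1:5]), 1.0)
  expect_equal(overlap_score(c("a", "b"), c("x", "y")), 0.0)
  expect_equal(overlap_score(c("a", "b", "c", "d"), letters[1:8]), 0.5)
  expect_error(overlap_score(character(0), "a"), "non-empty")

  withr::local_seed(12)
  for (rep in 1:20) {
    A <- sample(letters, sample(2:8, 1))
    B <- sample(letters, sample(2:8, 1))
    v <- overlap_score(A, B)
    expect_equal(v, overlap_score(B, A))  # symmetric
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_identical(v == 1, setequal(A, B))
  }
})

test_that("precision and recall count matched predictions and matched knowns", {
  known <- complex_catalog(tibble::tibble(
    complex_id = c("K1", "K2"),
    members = list(c("a", "b", "c"), c("x", "y", "z"))))

  # predictions identical to the catalog
  ev <- precision_recall(known$members, known)
  expect_equal(glance(ev)$precision, 1.0)
  expect_equal(glance(ev)$recall, 1.0)

  # two predictions matching only the first known complex
  ev2 <- precision_recall(list(c("a", "b", "c"), c("a", "b", "q")), known)
  expect_equal(glance(ev2)$precision, 1.0)
  expect_equal(glance(ev2)$recall, 0.5)
  expect_identical(glance(ev2)$matched_known, 1L)

  # matching is strictly greater-than at the threshold:
  # V({a,b},{a,c}) = 1/4 = 0.25 exactly -> unmatched
  known3 <- complex_catalog(tibble::tibble(complex_id = "K",
                                           members = list(c("a", "c"))))
  ev3 <- precision_recall(list(c("a", "b")), known3, threshold = 0.25)
  expect_equal(tidy(ev3)$best_v, 0.25)
  expect_false(tidy(ev3)$matched)
  expect_equal(glance(ev3)$precision, 0)

  # order invariance
  preds <- list(c("a", "b", "c"), c("x", "y"), c("a", "q", "r"))
  g1 <- glance(precision_recall(preds, known))
  g2 <- glance(precision_recall(rev(preds), known))
  expect_equal(g1, g2)

  # degenerate input
  expect_warning(ev0 <- precision_recall(list(), known), "no predictions")
  expect_equal(glance(ev0)$precision, 0)
  expect_equal(glance(ev0)$recall, 0)
})

test_that("same-function ratio counts informative within-complex pairs", {
  go <- go_annotation(tibble::tibble(
    gene = c("a", "b", "c", "u1", "u2", "u3"),
    term = c("GO:0000001", "GO:0000001", "GO:0000002",
             "GO:0003674", "GO:0005554", "GO:0003674")))
  expect_equal(same_function_ratio(list(c("a", "b")), go), 1.0)
  # terms {a},{a},{b}: only pair (1,2) of the three shares
  expect_equal(same_function_ratio(list(c("a", "b", "c")), go), 1 / 3)
  # complexes of unknown-function proteins contribute nothing
  expect_true(is.na(same_function_ratio(list(c("u1", "u2", "u3")), go)))
  # mixed: the unknown-function member is excluded from the denominator
  expect_equal(same_function_ratio(list(c("a", "b", "u1")), go), 1.0)
})

test_that("false-negative accounting subtracts DDI-less complexes", {
  known <- complex_catalog(tibble::tibble(
    complex_id = paste0("K", 1:5),
    members = list(c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                   c("c1", "c2", "c3"), c("d1", "d2", "d3"),
                   c("e1", "e2", "e3"))))
  dom <- domain_annotation(tibble::tibble(
    protein = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    domain_type = rep(c("u", "v"), 4)))
  cats <- ddi_catalog(tibble::tibble(domain_a = "u", domain_b = "v"))

  existing <- known$members[1:4]   # matches K1..K4, K5 unmatched

  # ours == existing: no net false negatives
  fn0 <- false_negative_report(existing, existing, known, dom, cats)
  expect_identical(fn0$alpha, 0L)
  expect_equal(fn0$ratio, 0)
  expect_identical(fn0$beta, 4L)

  # ours misses K4 although its members have cognate DDIs -> alpha 1, 1/4
  ours <- known$members[1:3]
  fn1 <- false_negative_report(existing, ours, known, dom, cats)
  expect_identical(fn1$net_fn, 1L)
  expect_identical(fn1$alpha, 1L)
  expect_equal(fn1$ratio, 0.25)

  # a missed known complex with no DDI annotation is excluded from alpha
  known2 <- complex_catalog(tibble::tibble(
    complex_id = c("K1", "K2"),
    members = list(c("a1", "a2", "a3"), c("n1", "n2", "n3"))))
  fn2 <- false_negative_report(known2$members, known2$members[1], known2,
                               dom, cats)
  expect_identical(fn2$net_fn, 1L)
  expect_identical(fn2$no_ddi_excluded, 1L)
  expect_identical(fn2$alpha, 0L)
})

test_that("function suggestion requires exactly one uncharacterized member and consensus", {
  go <- go_annotation(tibble::tibble(
    gene = c("APL1", "APS2", "APL3", "g1", "g2"),
    term = c("GO:0008565", "GO:0008565", "GO:0008565",
             "GO:0000010", "GO:0000020")))
  # one unknown member, others share the transporter term
  sug <- suggest_functions(list(c("APL1", "APS2", "APM4", "APL3")), go)
  expect_identical(nrow(sug), 1L)
  expect_identical(sug$uncharacterized, "APM4")
  expect_identical(sug$suggested_terms[[1]], "GO:0008565")

  # a member annotated only "function unknown" counts as uncharacterized
  go2 <- go_annotation(dplyr::bind_rows(
    tibble::tibble(gene = "APM4", term = "GO:0003674"),
    tibble::tibble(gene = c("APL1", "APS2", "APL3"), term = "GO:0008565")))
  sug2 <- suggest_functions(list(c("APL1", "APS2", "APM4", "APL3")), go2)
  expect_identical(sug2$uncharacterized, "APM4")

  # two uncharacterized members: no suggestion
  expect_identical(nrow(suggest_functions(list(c("APL1", "u1", "u2")), go)), 0L)
  # characterized members without a common term: no suggestion
  expect_identical(nrow(suggest_functions(list(c("g1", "g2", "u1")), go)), 0L)
})
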
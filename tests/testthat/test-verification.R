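test_that("a solved feasible candidate becomes one verified 3-protein complex", {
  fx <- worked_example_fixture()
  m <- build_binding_model(c("p1", "p2", "p3"), fx$network, fx$domains, fx$ddis)
  vc <- extract_verified(c("p1", "p2", "p3"), solve_binding(m))
  expect_identical(nrow(vc), 1L)
  expect_identical(vc$members[[1]], c("p1", "p2", "p3"))
  expect_identical(nrow(vc$ppi_edges[[1]]), 2L)
  expect_identical(nrow(vc$ddi_edges[[1]]), 2L)
})

test_that("the decoy triangle is rejected: one active edge is not a complex", {
  dc <- decoy_triangle()
  m <- build_binding_model(c("p", "q", "r"), dc$network, dc$domains, dc$ddis)
  vc <- extract_verified(c("p", "q", "r"), solve_binding(m))
  expect_identical(nrow(vc), 0L)
})

test_that("the sufficient-domain triangle is verified with all three PPIs", {
  sf <- sufficient_triangle()
  m <- build_binding_model(c("p", "q", "r"), sf$network, sf$domains, sf$ddis)
  s <- solve_binding(m)
  expect_identical(s$objective, 3L)
  vc <- extract_verified(c("p", "q", "r"), s)
  expect_identical(nrow(vc), 1L)
  expect_identical(nrow(vc$ppi_edges[[1]]), 3L)
})

test_that("candidates without DDI variables yield nothing", {
  net <- ppi_network(tibble::tibble(a = c("a", "a"), b = c("b", "c")))
  dom <- domain_annotation(tibble::tibble(protein = character(),
                                          domain_type = character()))
  cat <- ddi_catalog(tibble::tibble(domain_a = character(),
                                    domain_b = character()))
  m <- build_binding_model(c("a", "b", "c"), net, dom, cat)
  expect_identical(nrow(extract_verified(c("a", "b", "c"), solve_binding(m))), 0L)
})

test_that("verify_all composes, dedups and accounts for the reduction", {
  fx <- worked_example_fixture()
  dc <- decoy_triangle()
  net <- ppi_network(dplyr::bind_rows(
    tibble::tibble(a = fx$network$protein_a, b = fx$network$protein_b),
    tibble::tibble(a = dc$network$protein_a, b = dc$network$protein_b)))
  dom <- domain_annotation(dplyr::bind_rows(
    fx$domains[, c("protein", "domain_type")],
    dc$domains[, c("protein", "domain_type")]))
  cats <- ddi_catalog(dplyr::bind_rows(
    tibble::tibble(domain_a = fx$ddis$domain_a, domain_b = fx$ddis$domain_b),
    tibble::tibble(domain_a = dc$ddis$domain_a, domain_b = dc$ddis$domain_b)))
  f <- write_lines_tmp(c("p1 p2 p3", "p q r"))
  cands <- import_clusters(f, net)
  res <- verify_all(cands, net, dom, cats)
  expect_identical(res$summary$n_verified, 1L)
  expect_equal(res$summary$reduction_rate, 0.5)
  expect_identical(glance(res), res$summary)
  expect_identical(tidy(res), res$verified)
  expect_identical(res$per_candidate$accepted, c(TRUE, FALSE))

  # two candidates yielding the same member set collapse to one complex
  f2 <- write_lines_tmp(c("p1 p2 p3", "p1 p2 p3"))
  res2 <- verify_all(import_clusters(f2, net), net, dom, cats)
  expect_identical(res2$summary$n_verified, 1L)

  # empty candidate list -> empty output
  f3 <- write_lines_tmp(character(0))
  res3 <- verify_all(import_clusters(f3, net), net, dom, cats)
  expect_identical(res3$summary$n_verified, 0L)
  expect_identical(nrow(res3$verified), 0L)
})

test_that("verified complexes satisfy their structural invariants independently", {
  sim <- generate_scenario(synthetic_scenario(seed = 3))
  res <- verify_all(cc_cluster(sim$network), sim$network, sim$domains, sim$ddis)
  expect_gt(nrow(res$verified), 0L)
  for (i in seq_len(nrow(res$verified))) {
    r <- res$verified[i, ]
    pe <- r$ppi_edges[[1]]
    de <- r$ddi_edges[[1]]
    expect_gte(r$n_proteins, 3L)
    # members are exactly the endpoints of the active PPIs
    expect_identical(r$members[[1]], sort(unique(c(pe$protein_a, pe$protein_b))))
    # the active-PPI graph is connected
    g <- igraph::graph_from_data_frame(as.data.frame(pe), directed = FALSE)
    expect_equal(igraph::components(g)$no, 1)
    # each active PPI mediated by exactly one active DDI
    ppi_keys <- paste(pe$protein_a, pe$protein_b)
    ddi_keys <- paste(pmin(de$protein_i, de$protein_j),
                      pmax(de$protein_i, de$protein_j))
    expect_setequal(ddi_keys, ppi_keys)
    expect_identical(anyDuplicated(ddi_keys), 0L)
    # exclusivity re-checked outside the solver
    inst <- c(paste0(de$protein_i, ":", de$domain_i, "/", de$copy_i),
              paste0(de$protein_j, ":", de$domain_j, "/", de$copy_j))
    expect_identical(anyDuplicated(inst), 0L)
  }
})

test_that("enlarging the DDI catalog never flips verified to rejected", {
  withr::local_seed(71)
  for (rep in 1:10) {
    rm_ <- random_model(max_vars = 10)
    inst <- rm_$inst
    vc0 <- extract_verified(inst$members, solve_binding(rm_$model))
    extra <- sample(paste0("t", 1:4), 2, replace = TRUE)
    ddis2 <- ddi_catalog(tibble::tibble(
      domain_a = c(inst$ddis$domain_a, extra[1]),
      domain_b = c(inst$ddis$domain_b, extra[2])))
    m2 <- build_binding_model(inst$members, inst$network, inst$domains, ddis2)
    vc2 <- extract_verified(inst$members, solve_binding(m2))
    if (nrow(vc0) > 0) expect_gte(nrow(vc2), 1L)
  }
})
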
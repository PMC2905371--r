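# Shared fixtures and independent checkers for the suite. Everything is
# built in code; no stored data files.

# triangle decoy: three proteins, one domain each, catalog allows all three
# type pairs — only one DDI can ever be active at a time
decoy_triangle <- function() {
  list(
    network = ppi_network(tibble::tibble(a = c("p", "p", "q"),
                                         b = c("q", "r", "r"))),
    domains = domain_annotation(tibble::tibble(
      protein = c("p", "q", "r"), domain_type = c("dp", "dq", "dr"))),
    ddis = ddi_catalog(tibble::tibble(domain_a = c("dp", "dp", "dq"),
                                      domain_b = c("dq", "dr", "dr")))
  )
}

# triangle with sufficient domains: each protein carries one dedicated
# interface per partner, so all three PPIs are simultaneously realizable
sufficient_triangle <- function() {
  list(
    network = ppi_network(tibble::tibble(a = c("p", "p", "q"),
                                         b = c("q", "r", "r"))),
    domains = domain_annotation(tibble::tibble(
      protein = c("p", "p", "q", "q", "r", "r"),
      domain_type = c("dpq", "dpr", "dqp", "dqr", "drp", "drq"))),
    ddis = ddi_catalog(tibble::tibble(domain_a = c("dpq", "dpr", "dqr"),
                                      domain_b = c("dqp", "drp", "drq")))
  )
}

# random small binding-model instance for property tests; the domain-type
# pool is small so homotypic pairs and shared interfaces occur naturally
random_instance <- function(n_proteins = sample(3:5, 1),
                            edge_prob = 0.7,
                            max_instances = 2,
                            type_pool = paste0("t", 1:4),
                            catalog_pairs = 4) {
  prots <- paste0("r", seq_len(n_proteins))
  cmb <- utils::combn(prots, 2)
  on <- stats::runif(ncol(cmb)) < edge_prob
  if (!any(on)) on[sample.int(length(on), 1)] <- TRUE
  dom <- do.call(rbind, lapply(prots, function(p) {
    k <- sample.int(max_instances, 1)
    data.frame(protein = p,
               domain_type = sample(type_pool, k, replace = TRUE))
  }))
  all_pairs <- utils::combn(c(type_pool, type_pool[1]), 2)  # includes a homotypic chance
  pick <- sample.int(ncol(all_pairs), min(catalog_pairs, ncol(all_pairs)))
  list(
    network = ppi_network(tibble::tibble(a = cmb[1, on], b = cmb[2, on]),
                          proteins = prots),
    domains = domain_annotation(dom),
    ddis = ddi_catalog(tibble::tibble(domain_a = all_pairs[1, pick],
                                      domain_b = all_pairs[2, pick])),
    members = prots
  )
}

random_model <- function(..., max_vars = 12) {
  repeat {
    inst <- random_instance(...)
    m <- build_binding_model(inst$members, inst$network, inst$domains,
                             inst$ddis)
    if (nrow(m$ddi_vars) <= max_vars) return(list(model = m, inst = inst))
  }
}

# independent feasibility check of a solution against the model's stated
# constraints: binary values, every domain instance in at most one active
# DDI, at most one active DDI per protein pair, objective = active pairs
check_solution_feasible <- function(model, solution) {
  v <- solution$assignment$value
  expect_true(all(v %in% c(0L, 1L)))
  active <- model$ddi_vars[v == 1L, , drop = FALSE]
  inst <- c(sprintf("%s:%s/%d", active$protein_i, active$domain_i, active$copy_i),
            sprintf("%s:%s/%d", active$protein_j, active$domain_j, active$copy_j))
  expect_true(anyDuplicated(inst) == 0)
  expect_true(anyDuplicated(active$pair_id) == 0)
  expect_identical(solution$objective, length(unique(active$pair_id)))
  expect_identical(nrow(solution$active_ppis), solution$objective)
}

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
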
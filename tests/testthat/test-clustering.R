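two_triangles <- function() {
  ppi_network(tibble::tibble(a = c("a", "a", "b", "x", "x", "y"),
                             b = c("b", "c", "c", "y", "z", "z")))
}

test_that("MCL separates disjoint dense components", {
  cl <- mcl_cluster(two_triangles())  # default inflation
  expect_identical(nrow(cl), 2L)
  expect_setequal(cl$members[[1]], c("a", "b", "c"))
  expect_setequal(cl$members[[2]], c("x", "y", "z"))
  expect_identical(formals(mcl_cluster)$inflation, 3.6)
})

test_that("MCL handles a single edge and rejects bad inflation", {
  net <- ppi_network(tibble::tibble(a = "A", b = "B"))
  cl <- mcl_cluster(net)
  expect_identical(nrow(cl), 1L)
  expect_setequal(cl$members[[1]], c("A", "B"))
  expect_error(mcl_cluster(net, inflation = 1), "inflation")
})

test_that("MCL clusters partition the proteins and never span components", {
  withr::local_seed(42)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    prots <- paste0("n", seq_len(n))
    cmb <- utils::combn(prots, 2)
    on <- stats::runif(ncol(cmb)) < 0.15
    if (!any(on)) on[1] <- TRUE
    net <- ppi_network(tibble::tibble(a = cmb[1, on], b = cmb[2, on]))
    cl <- mcl_cluster(net)
    all_mem <- unlist(cl$members)
    expect_setequal(all_mem, network_proteins(net))
    expect_identical(anyDuplicated(all_mem), 0L)
    g <- igraph::graph_from_data_frame(
      as.data.frame(net[, c("protein_a", "protein_b")]), directed = FALSE,
      vertices = network_proteins(net))
    comp <- igraph::components(g)$membership
    for (m in cl$members) {
      expect_identical(length(unique(comp[m])), 1L)
    }
  }
})

test_that("clustering coefficient matches a brute-force triangle count", {
  tri <- ppi_network(tibble::tibble(a = c("a", "a", "b"), b = c("b", "c", "c")))
  expect_equal(clustering_coefficient(tri, "a"), 1.0)
  star <- ppi_network(tibble::tibble(a = c("s", "s", "s"), b = c("x", "y", "z")))
  expect_equal(clustering_coefficient(star, "s"), 0.0)
  third <- ppi_network(tibble::tibble(a = c("v", "v", "v", "a"),
                                      b = c("a", "b", "c", "b")))
  expect_equal(clustering_coefficient(third, "v"), 1 / 3)
  expect_error(clustering_coefficient(tri, "nope"), "Unknown protein")

  # brute force on random graphs: count neighbor-neighbor edges directly
  withr::local_seed(7)
  for (rep in 1:3) {
    n <- sample(20:50, 1)
    prots <- paste0("g", seq_len(n))
    cmb <- utils::combn(prots, 2)
    on <- stats::runif(ncol(cmb)) < 0.1
    net <- ppi_network(tibble::tibble(a = cmb[1, on], b = cmb[2, on]))
    keys <- paste(net$protein_a, net$protein_b)
    for (p in sample(network_proteins(net), 5)) {
      nb <- sort(unique(c(net$protein_b[net$protein_a == p],
                          net$protein_a[net$protein_b == p])))
      expected <- if (length(nb) < 2) 0 else {
        prs <- utils::combn(nb, 2)
        sum(paste(pmin(prs[1, ], prs[2, ]), pmax(prs[1, ], prs[2, ])) %in% keys) /
          ncol(prs)
      }
      expect_equal(clustering_coefficient(net, p), expected)
    }
  }
})

test_that("cc_cluster emits deduplicated seed neighborhoods", {
  tri <- ppi_network(tibble::tibble(a = c("a", "a", "b"), b = c("b", "c", "c")))
  cl <- cc_cluster(tri)  # default threshold 0.4
  expect_identical(nrow(cl), 1L)
  expect_setequal(cl$members[[1]], c("a", "b", "c"))
  expect_identical(formals(cc_cluster)$threshold, 0.4)

  path <- ppi_network(tibble::tibble(a = c("a", "b"), b = c("b", "c")))
  expect_identical(nrow(cc_cluster(path, 0.4)), 0L)
  expect_error(cc_cluster(tri, 1.5), "threshold")
})

test_that("cc_cluster is invariant under protein relabeling", {
  withr::local_seed(99)
  n <- 12
  prots <- paste0("p", seq_len(n))
  cmb <- utils::combn(prots, 2)
  on <- stats::runif(ncol(cmb)) < 0.3
  net <- ppi_network(tibble::tibble(a = cmb[1, on], b = cmb[2, on]))
  relabel <- stats::setNames(paste0("q", sample(seq_len(n))), prots)
  net2 <- ppi_network(tibble::tibble(a = relabel[net$protein_a],
                                     b = relabel[net$protein_b]))
  cl1 <- lapply(cc_cluster(net)$members, function(m) sort(unname(relabel[m])))
  cl2 <- cc_cluster(net2)$members
  expect_setequal(lapply(cl1, paste, collapse = " "),
                  lapply(cl2, paste, collapse = " "))
})

test_that("import_clusters validates members against the network", {
  net <- ppi_network(tibble::tibble(a = c("p1", "p1"), b = c("p2", "p3")))
  f <- write_lines_tmp(c("p1 p2 p3", "p1\tp2\tunknown"))
  expect_warning(cl <- import_clusters(f, net), "unknown")
  expect_identical(nrow(cl), 2L)
  expect_setequal(cl$members[[1]], c("p1", "p2", "p3"))
  expect_setequal(cl$members[[2]], c("p1", "p2"))
  f2 <- write_lines_tmp(character(0))
  expect_identical(nrow(import_clusters(f2, net)), 0L)
  expect_error(import_clusters("/nonexistent/file", net), "not found")
})
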
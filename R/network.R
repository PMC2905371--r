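#' Protein-protein interaction network
#'
#' A `ppi_network` is a tibble of undirected experimental PPI edges — the set
#' of potential interactions that the verification step is allowed to switch
#' on. Each row is one edge with the lexicographically smaller protein id in
#' `protein_a`, so the edge set is canonical: no self loops, no duplicated
#' `(a,b)`/`(b,a)` rows. The full protein set (which may include isolated
#' proteins) is carried in the `proteins` attribute.
#'
#' @param edges A data frame with two character columns giving the endpoints
#'   of each edge. Extra columns are dropped.
#' @param proteins Optional character vector of protein ids; defaults to the
#'   union of edge endpoints. Endpoints missing from `proteins` are an error.
#'
#' @return A `ppi_network` tibble with columns `protein_a`, `protein_b`.
#' @export
#' @examples
#' net <- ppi_network(data.frame(a = c("B", "A"), b = c("A", "C")))
#' net
#' network_proteins(net)
ppi_network <- function(edges, proteins = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    abort("`edges` needs at least two columns (the two interacting proteins).")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  tb <- distinct(tibble(protein_a = lo, protein_b = hi))
  tb <- arrange(tb, .data$protein_a, .data$protein_b)
  prots <- sort(unique(c(proteins, tb$protein_a, tb$protein_b)))
  missing <- setdiff(c(tb$protein_a, tb$protein_b), prots)
  if (length(missing) > 0) {
    abort(paste0("Edge endpoints absent from `proteins`: ",
                 paste(missing, collapse = ", ")))
  }
  new_tibble(tb, proteins = prots, class = "ppi_network")
}

#' @rdname ppi_network
#' @param x A `ppi_network`.
#' @export
network_proteins <- function(x) {
  stopifnot(inherits(x, "ppi_network"))
  attr(x, "proteins")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("# PPI network: %d proteins, %d edges\n",
              length(network_proteins(x)), nrow(x)))
  print(as_tibble(x), ...)
  invisible(x)
}

# igraph view of the network, keeping isolated proteins as vertices
as_igraph_network <- function(network) {
  igraph::graph_from_data_frame(
    as.data.frame(network[, c("protein_a", "protein_b")]),
    directed = FALSE,
    vertices = network_proteins(network)
  )
}

# canonical unordered-pair key, used for protein pairs and domain-type pairs
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\x1f")

# member sets from the containers that carry complexes: a candidate_set /
# verified tibble with a `members` list column, a complex_catalog, or a bare
# list of character vectors
member_sets <- function(x) {
  if (is.data.frame(x) && "members" %in% names(x)) {
    out <- x$members
  } else if (is.list(x) && !is.data.frame(x)) {
    out <- x
  } else {
    abort("Cannot extract member sets: expected a `members` list column or a list of character vectors.")
  }
  lapply(out, function(m) sort(unique(as.character(m))))
}
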
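# Synthetic benchmark generator with planted ground truth. True complexes
# are cliques built witness-first: the feasible DDI assignment is constructed
# explicitly (one fresh cognate domain-type pair per clique edge, one
# instance per endpoint), then the domain annotation and catalog are emitted
# from it, so planted feasibility is guaranteed by construction rather than
# by a solver call. Decoys are cliques whose members each carry exactly one
# promiscuous domain, so binding-interface exclusivity caps their active
# PPIs at floor(size / 2) and verification must reject them.

# evaluate code under a seed, restoring the caller's RNG state afterwards
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Define a synthetic benchmark scenario
#'
#' Describes a planted-truth benchmark: `n_true` feasible complexes (cliques
#' whose members carry enough pairwise-cognate domain instances that every
#' clique PPI is simultaneously realizable), `n_decoys` domain-starved decoy
#' cliques, and an Erdős–Rényi background layer. Generation is a pure
#' function of `seed`.
#'
#' @param n_true Number of planted feasible complexes. Default 10.
#' @param size_range Inclusive size range for planted complexes (min >= 3).
#'   Default `c(3, 6)`.
#' @param n_decoys Number of domain-starved decoy cliques. Default 10.
#' @param decoy_size_range Inclusive size range for decoys (min >= 3).
#'   Default `c(3, 5)`.
#' @param n_background Number of background proteins. Default 40.
#' @param bg_edge_prob Erdős–Rényi edge probability among background
#'   proteins. Default 0.03.
#' @param decoy_mode `"promiscuous"` (each decoy member carries one copy of
#'   the clique's single promiscuous self-interacting domain type) or
#'   `"none"` (decoy members carry no usable domain at all). Default
#'   `"promiscuous"`.
#' @param seed Integer seed driving every random draw. Default 1.
#'
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_true = 10, size_range = c(3, 6),
                               n_decoys = 10, decoy_size_range = c(3, 5),
                               n_background = 40, bg_edge_prob = 0.03,
                               decoy_mode = c("promiscuous", "none"),
                               seed = 1) {
  decoy_mode <- match.arg(decoy_mode)
  if (n_true < 0 || n_decoys < 0 || n_background < 0) {
    abort("Counts must be >= 0.")
  }
  if (bg_edge_prob < 0 || bg_edge_prob > 1) {
    abort("`bg_edge_prob` must be in [0, 1].")
  }
  check_range <- function(r, what) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 3) {
      abort(paste0("`", what, "` must be c(min, max) with 3 <= min <= max."))
    }
  }
  check_range(size_range, "size_range")
  check_range(decoy_size_range, "decoy_size_range")
  structure(list(n_true = n_true, size_range = size_range,
                 n_decoys = n_decoys, decoy_size_range = decoy_size_range,
                 n_background = n_background, bg_edge_prob = bg_edge_prob,
                 decoy_mode = decoy_mode, seed = seed),
            class = "synthetic_scenario")
}

# sample one integer from an inclusive range (safe when lo == hi)
sample_size <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

clique_edges <- function(members) {
  cmb <- utils::combn(sort(members), 2)
  tibble(a = cmb[1, ], b = cmb[2, ])
}

#' Generate a synthetic benchmark
#'
#' Materializes a [synthetic_scenario()] into the five pipeline inputs plus
#' the planted truth. The feasibility witness of every planted complex is
#' validated against the exclusivity and pair constraints during generation.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A list: `network` ([ppi_network()]), `domains`
#'   (`domain_annotation`), `ddis` (`ddi_catalog`), `known`
#'   (`complex_catalog` of the planted true complexes), `go`
#'   (`go_annotation`), and `truth` (tibble: `complex_id`, `kind`,
#'   `members`).
#' @export
#' @examples
#' sim <- generate_scenario(synthetic_scenario(n_true = 2, n_decoys = 1,
#'                                             n_background = 0, seed = 7))
#' sim$network
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_rng_seed(scenario$seed, {
    edges <- list()
    dom <- list()
    cat <- list()
    go <- list()
    truth <- list()

    # planted feasible complexes, witness-first
    for (c in seq_len(scenario$n_true)) {
      s <- sample_size(scenario$size_range[1], scenario$size_range[2])
      mem <- sprintf("T%02d_%02d", c, seq_len(s))
      ce <- clique_edges(mem)
      witness_inst <- character(0)
      for (e in seq_len(nrow(ce))) {
        ta <- sprintf("dt%02de%02da", c, e)
        tb <- sprintf("dt%02de%02db", c, e)
        dom[[length(dom) + 1]] <- tibble(protein = c(ce$a[e], ce$b[e]),
                                         domain_type = c(ta, tb))
        cat[[length(cat) + 1]] <- tibble(domain_a = ta, domain_b = tb)
        witness_inst <- c(witness_inst, paste0(ce$a[e], ":", ta),
                          paste0(ce$b[e], ":", tb))
      }
      # witness validity: every edge covered, no instance reused
      stopifnot(!anyDuplicated(witness_inst),
                length(witness_inst) == 2 * nrow(ce))
      edges[[length(edges) + 1]] <- ce
      go[[length(go) + 1]] <- tibble(gene = mem,
                                     term = sprintf("GO:%07d", 1000000 + c))
      truth[[length(truth) + 1]] <- tibble(complex_id = sprintf("K%02d", c),
                                           kind = "true", members = list(mem))
    }

    # domain-starved decoy cliques
    for (c in seq_len(scenario$n_decoys)) {
      s <- sample_size(scenario$decoy_size_range[1], scenario$decoy_size_range[2])
      mem <- sprintf("X%02d_%02d", c, seq_len(s))
      edges[[length(edges) + 1]] <- clique_edges(mem)
      if (scenario$decoy_mode == "promiscuous") {
        tx <- sprintf("dx%02d", c)
        dom[[length(dom) + 1]] <- tibble(protein = mem, domain_type = tx)
        cat[[length(cat) + 1]] <- tibble(domain_a = tx, domain_b = tx)
      }
      go[[length(go) + 1]] <- tibble(
        gene = mem, term = sprintf("GO:%07d", 2000000 + sample.int(50, s, replace = TRUE)))
      truth[[length(truth) + 1]] <- tibble(complex_id = sprintf("D%02d", c),
                                           kind = "decoy", members = list(mem))
    }

    # Erdős–Rényi background layer
    bg <- sprintf("B%03d", seq_len(scenario$n_background))
    if (length(bg) >= 2 && scenario$bg_edge_prob > 0) {
      cmb <- utils::combn(bg, 2)
      on <- runif(ncol(cmb)) < scenario$bg_edge_prob
      if (any(on)) {
        edges[[length(edges) + 1]] <- tibble(a = cmb[1, on], b = cmb[2, on])
      }
    }
    if (length(bg) > 0) {
      dom[[length(dom) + 1]] <- tibble(protein = bg,
                                       domain_type = sprintf("dbg%03d", seq_along(bg)))
      unknown <- runif(length(bg)) < 0.1
      go[[length(go) + 1]] <- tibble(
        gene = bg,
        term = ifelse(unknown, "GO:0003674",
                      sprintf("GO:%07d", 2000000 + sample.int(50, length(bg),
                                                              replace = TRUE))))
    }

    edges <- bind_rows(edges)
    all_prots <- sort(unique(c(edges$a, edges$b, bg)))
    truth <- bind_rows(truth)
    known <- truth[truth$kind == "true", , drop = FALSE]
    dom_tb <- bind_rows(dom)
    if (nrow(dom_tb) == 0) {
      dom_tb <- tibble(protein = character(), domain_type = character())
    }
    cat_tb <- bind_rows(cat)
    if (nrow(cat_tb) == 0) {
      cat_tb <- tibble(domain_a = character(), domain_b = character())
    }
    list(
      network = ppi_network(edges, proteins = all_prots),
      domains = domain_annotation(dom_tb),
      ddis = ddi_catalog(cat_tb),
      known = complex_catalog(tibble(complex_id = known$complex_id,
                                     members = known$members)),
      go = go_annotation(bind_rows(go)),
      truth = truth
    )
  })
}

#' Write a generated scenario to a directory as pipeline-ready TSVs
#'
#' Emits `ppi.tsv`, `domains.tsv`, `ddis.tsv`, `known_complexes.tsv` and
#' `go.tsv` in the formats the readers expect. Output is byte-identical for
#' identical scenarios.
#'
#' @param data Output of [generate_scenario()].
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- data$network
  writeLines(c("# synthetic PPI edge list",
               sprintf("%s\t%s\tsynthetic", net$protein_a, net$protein_b)),
             file.path(dir, "ppi.tsv"))
  d <- dplyr::count(data$domains, .data$protein, .data$domain_type)
  writeLines(c("# synthetic domain annotation",
               sprintf("%s\t%s\t%d", d$protein, d$domain_type, d$n)),
             file.path(dir, "domains.tsv"))
  writeLines(c("# synthetic DDI catalog",
               sprintf("%s\t%s\tsynthetic", data$ddis$domain_a, data$ddis$domain_b)),
             file.path(dir, "ddis.tsv"))
  writeLines(c("# synthetic known complexes",
               sprintf("%s\t%s", data$known$complex_id,
                       map_chr(data$known$members, paste, collapse = ","))),
             file.path(dir, "known_complexes.tsv"))
  writeLines(c("# synthetic GO molecular-function annotation",
               sprintf("%s\t%s\tF", data$go$gene, data$go$term)),
             file.path(dir, "go.tsv"))
  invisible(dir)
}

#' The three-protein worked example
#'
#' The canonical small instance used throughout the documentation and tests:
#' protein `p1` carries domains `d1` and `d4`, proteins `p2` and `p3` carry
#' `d2` and `d3`; the network holds the two potential PPIs `p1-p2` and
#' `p1-p3`; the catalog allows `d1-d2`, `d4-d2`, `d1-d3` and `d4-d3`. Its
#' binding model has 2 PPI variables and 4 DDI variables, and both PPIs are
#' simultaneously realizable (objective 2) because `p1` can serve its two
#' partners through two different domains.
#'
#' @return A list with `network`, `domains`, `ddis`.
#' @export
worked_example_fixture <- function() {
  list(
    network = ppi_network(tibble(a = c("p1", "p1"), b = c("p2", "p3"))),
    domains = domain_annotation(tibble(
      protein = c("p1", "p1", "p2", "p3"),
      domain_type = c("d1", "d4", "d2", "d3"))),
    ddis = ddi_catalog(tibble(domain_a = c("d1", "d4", "d1", "d4"),
                              domain_b = c("d2", "d2", "d3", "d3")))
  )
}
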
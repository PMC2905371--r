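#' Build the binding model for a candidate complex
#'
#' Step 2 formulates "can these proteins all bind simultaneously?" as a
#' binary integer program over the candidate:
#'
#' * one binary PPI variable `P(i,j)` for every candidate protein pair that
#'   is present in the experimental PPI network (the potential-PPI set);
#' * one binary DDI variable `D(i,j,k)` for every pair of domain instances —
#'   one in protein `i`, one in protein `j` — whose domain types form a pair
#'   in the DDI catalog. Variables only span distinct proteins; a homotypic
#'   type pair needs two distinct instances.
#' * a pair constraint `P(i,j) = sum_k D(i,j,k)` for every pair with at
#'   least one DDI variable (a pair with none has `P` fixed to 0). Because
#'   `P` is binary, the equality also forbids two simultaneous DDIs across
#'   the same protein pair.
#' * an exclusivity constraint `sum D <= 1` over the DDI variables touching
#'   each domain instance — one binding interface engages at most one
#'   partner at a time. Instances whose variables all lie within a single
#'   protein pair are already capped by that pair's equality constraint, so
#'   only instances spanning two or more pairs contribute a constraint row.
#'
#' The objective is to maximize the number of simultaneously realizable
#' PPIs, i.e. the sum of the `P` variables.
#'
#' @param candidate Character vector of member protein ids (or a one-row
#'   slice of a `candidate_set`). At least 2 proteins.
#' @param network A [ppi_network()] containing the candidate members.
#' @param domains A `domain_annotation` ([read_domain_annotation()]).
#' @param ddis A `ddi_catalog` ([read_ddi_catalog()]).
#'
#' @return A `binding_model` with elements `members`, `ppi_vars` (tibble:
#'   `pair_id`, `protein_i`, `protein_j`, `fixed_zero`), `ddi_vars` (tibble:
#'   `ddi_id`, `pair_id`, the two domain instances), and `exclusivity`
#'   (tibble: `instance`, `ddi_ids` list).
#' @export
#' @examples
#' fx <- worked_example_fixture()
#' m <- build_binding_model(c("p1", "p2", "p3"), fx$network, fx$domains, fx$ddis)
#' m
build_binding_model <- function(candidate, network, domains, ddis) {
  members <- sort(unique(unlist(member_sets(list(candidate)))))
  if (length(members) < 2) abort("A candidate needs at least 2 proteins.")
  stopifnot(inherits(network, "ppi_network"))
  outside <- setdiff(members, network_proteins(network))
  if (length(outside) > 0) {
    abort(paste0("Candidate members not in the network: ",
                 paste(outside, collapse = ", ")))
  }

  # candidate pairs restricted to the experimental edge set
  edge_keys <- pair_key(network$protein_a, network$protein_b)
  combs <- utils::combn(members, 2)
  in_omega <- pair_key(combs[1, ], combs[2, ]) %in% edge_keys
  ppi_vars <- tibble(protein_i = combs[1, in_omega],
                     protein_j = combs[2, in_omega]) |>
    arrange(.data$protein_i, .data$protein_j) |>
    mutate(pair_id = paste0("P(", .data$protein_i, ",", .data$protein_j, ")"))

  inst <- domains[domains$protein %in% members, , drop = FALSE]
  cat_keys <- pair_key(ddis$domain_a, ddis$domain_b)

  ddi_vars <- vector("list", nrow(ppi_vars))
  for (r in seq_len(nrow(ppi_vars))) {
    pi <- ppi_vars$protein_i[r]
    pj <- ppi_vars$protein_j[r]
    di <- inst[inst$protein == pi, , drop = FALSE]
    dj <- inst[inst$protein == pj, , drop = FALSE]
    if (nrow(di) == 0 || nrow(dj) == 0) next
    grid <- tidyr::expand_grid(i = seq_len(nrow(di)), j = seq_len(nrow(dj)))
    ok <- pair_key(di$domain_type[grid$i], dj$domain_type[grid$j]) %in% cat_keys
    grid <- grid[ok, , drop = FALSE]
    if (nrow(grid) == 0) next
    ddi_vars[[r]] <- tibble(
      pair_id = ppi_vars$pair_id[r],
      protein_i = pi, domain_i = di$domain_type[grid$i], copy_i = di$copy[grid$i],
      protein_j = pj, domain_j = dj$domain_type[grid$j], copy_j = dj$copy[grid$j]
    )
  }
  ddi_vars <- bind_rows(ddi_vars)
  if (nrow(ddi_vars) == 0) {
    ddi_vars <- tibble(pair_id = character(), protein_i = character(),
                       domain_i = character(), copy_i = integer(),
                       protein_j = character(), domain_j = character(),
                       copy_j = integer())
  }
  ddi_vars <- ddi_vars |>
    distinct() |>
    arrange(.data$pair_id, .data$domain_i, .data$copy_i,
            .data$domain_j, .data$copy_j) |>
    mutate(ddi_id = sprintf("D(%s,%s:%s/%d,%s:%s/%d)",
                            sub("^P\\((.*)\\)$", "\\1", .data$pair_id),
                            .data$protein_i, .data$domain_i, .data$copy_i,
                            .data$protein_j, .data$domain_j, .data$copy_j))

  ppi_vars$fixed_zero <- !(ppi_vars$pair_id %in% ddi_vars$pair_id)

  # exclusivity rows: domain instances touched by DDI variables from >= 2
  # distinct protein pairs (single-pair instances are capped by the pair
  # equality already)
  instance_of <- function(p, d, c) paste0(p, ":", d, "/", c)
  long <- bind_rows(
    tibble(instance = instance_of(ddi_vars$protein_i, ddi_vars$domain_i,
                                  ddi_vars$copy_i),
           ddi_id = ddi_vars$ddi_id, pair_id = ddi_vars$pair_id),
    tibble(instance = instance_of(ddi_vars$protein_j, ddi_vars$domain_j,
                                  ddi_vars$copy_j),
           ddi_id = ddi_vars$ddi_id, pair_id = ddi_vars$pair_id)
  )
  exclusivity <- long |>
    group_by(.data$instance) |>
    summarise(ddi_ids = list(sort(unique(.data$ddi_id))),
              n_pairs = length(unique(.data$pair_id)), .groups = "drop") |>
    filter(.data$n_pairs >= 2) |>
    select("instance", "ddi_ids") |>
    arrange(.data$instance)

  structure(
    list(members = members,
         ppi_vars = select(ppi_vars, "pair_id", "protein_i", "protein_j",
                           "fixed_zero"),
         ddi_vars = select(ddi_vars, "ddi_id", "pair_id", "protein_i",
                           "domain_i", "copy_i", "protein_j", "domain_j",
                           "copy_j"),
         exclusivity = exclusivity),
    class = "binding_model"
  )
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("# Binding model: %d proteins, %d PPI variables (%d with cognate DDIs), %d DDI variables, %d exclusivity constraints\n",
              length(x$members), nrow(x$ppi_vars),
              sum(!x$ppi_vars$fixed_zero), nrow(x$ddi_vars),
              nrow(x$exclusivity)))
  invisible(x)
}

#' Render a binding model as human-readable LP text
#'
#' Debugging aid: the objective, pair equalities, fixed-zero pairs and
#' exclusivity rows in an LP-like plain-text layout.
#'
#' @param model A `binding_model`.
#' @return A character vector of lines, invisibly printed with `cat()` when
#'   at top level.
#' @export
format_lp <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  lines <- c(
    paste0("maximize ", paste(model$ppi_vars$pair_id, collapse = " + ")),
    "subject to"
  )
  for (r in seq_len(nrow(model$ppi_vars))) {
    pid <- model$ppi_vars$pair_id[r]
    if (model$ppi_vars$fixed_zero[r]) {
      lines <- c(lines, paste0("  ", pid, " = 0"))
    } else {
      ds <- model$ddi_vars$ddi_id[model$ddi_vars$pair_id == pid]
      lines <- c(lines, paste0("  ", pid, " = ", paste(ds, collapse = " + ")))
    }
  }
  for (r in seq_len(nrow(model$exclusivity))) {
    lines <- c(lines, paste0("  ",
                             paste(model$exclusivity$ddi_ids[[r]], collapse = " + "),
                             " <= 1   [", model$exclusivity$instance[r], "]"))
  }
  lines <- c(lines, "binary all variables")
  structure(lines, class = "lp_text")
}

#' @export
print.lp_text <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}
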